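#' U-Net configuration
#'
#' Configuration of the 1D noise-prediction network: a symmetric
#' encoder-decoder with residual blocks, optional self-attention per
#' resolution level, skip connections concatenating encoder feature maps
#' into the decoder, and a two-branch output head predicting the noise
#' \eqn{\epsilon_\theta} and the variance-interpolation coefficient
#' \eqn{v_\theta}. Timestep (and optionally label) embeddings are injected
#' additively into every residual block; a conditioning signal, when
#' present, is concatenated channel-wise with the input and consumed
#' directly by the stem convolution.
#'
#' @param length Signal length; must be divisible by `2^(n_levels - 1)`.
#' @param in_channels Channels of the modelled signal.
#' @param base_channels Channel width at the first level.
#' @param channel_mults Per-level channel multipliers; their count sets the
#'   number of resolution levels.
#' @param n_res_blocks_per_level Residual blocks per level.
#' @param attention Logical vector (recycled) enabling self-attention per
#'   level; the bottleneck always has attention.
#' @param time_embed_dim Dimension of the sinusoidal timestep embedding
#'   (even).
#' @param n_classes Class count for label conditioning, or `NULL`.
#' @param cond_channels Channels of the conditioning signal, or `NULL`/0
#'   for none. Label and signal conditioning are mutually exclusive.
#' @return A `unet_config` list.
#' @export
unet_config <- function(length, in_channels = 1, base_channels = 16,
                        channel_mults = c(1, 2, 4),
                        n_res_blocks_per_level = 1,
                        attention = c(FALSE, FALSE, TRUE),
                        time_embed_dim = 32,
                        n_classes = NULL, cond_channels = NULL) {
  n_levels <- length(channel_mults)
  if (length %% 2L^(n_levels - 1L) != 0L) {
    stopf("length %d not divisible by the downsampling factor %d",
          length, 2L^(n_levels - 1L))
  }
  if (time_embed_dim %% 2L != 0L) stopf("time_embed_dim must be even")
  if (!is.null(n_classes) && !is.null(cond_channels) && cond_channels > 0) {
    stopf("label and signal conditioning are mutually exclusive")
  }
  attention <- rep_len(as.logical(attention), n_levels)
  structure(list(length = as.integer(length),
                 in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 channel_mults = as.integer(channel_mults),
                 n_levels = n_levels,
                 n_res_blocks = as.integer(n_res_blocks_per_level),
                 attention = attention,
                 time_embed_dim = as.integer(time_embed_dim),
                 n_classes = if (!is.null(n_classes)) as.integer(n_classes),
                 cond_channels = if (!is.null(cond_channels)) as.integer(cond_channels)),
            class = "unet_config")
}

#' Sinusoidal timestep embedding
#'
#' Transformer-style position encoding of diffusion timesteps: for
#' dimension `d`, the first `d/2` entries are sines and the last `d/2`
#' cosines of the timestep scaled by geometrically spaced frequencies, so
#' `t = 0` maps to (0, ..., 0, 1, ..., 1). Inside the network this fixed
#' encoding is followed by a learned two-layer projection.
#'
#' @param t Integer timestep(s).
#' @param dim Even embedding dimension.
#' @return A `(dim, length(t))` matrix.
#' @export
embed_timestep <- function(t, dim) {
  if (dim %% 2 != 0) stopf("embedding dim must be even")
  half <- dim %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / max(1L, half - 1L))
  arg <- freqs %o% as.numeric(t)
  rbind(sin(arg), cos(arg))
}

#' Label embedding lookup
#'
#' Looks up learned class embeddings (one column per class) that are added
#' to the timestep embedding before it enters the residual blocks.
#'
#' @param label Integer labels, 0-based.
#' @param n_classes Number of classes.
#' @param table Embedding matrix `(dim, n_classes)`.
#' @return Matrix `(dim, length(label))`.
#' @export
inject_label <- function(label, n_classes, table) {
  if (any(label < 0L | label >= n_classes)) {
    stopf("label out of range [0, %d)", n_classes)
  }
  table[, label + 1L, drop = FALSE]
}

#' Fuse a conditioning signal with the sampling state
#'
#' Channel-wise concatenation of the current state `xt` with the
#' conditioning signal, followed by a width-1 convolution mapping back to
#' the model's input channel count. With fusing weights `[I 0]` this
#' reduces exactly to the unconditional input path.
#'
#' @param xt State array `(C, L, B)`.
#' @param cond_signal Conditioning array `(C_cond, L, B)`.
#' @param W,b Fusing convolution weight `(C, (C + C_cond))` and bias.
#' @return Array `(C, L, B)`.
#' @export
inject_signal_condition <- function(xt, cond_signal, W, b = numeric(nrow(W))) {
  if (!identical(dim(xt)[2:3], dim(cond_signal)[2:3])) {
    stopf("conditioning signal length/batch mismatch")
  }
  hc <- cat_channels(xt, cond_signal)
  conv1d_fw(hc, W, b, stride = 1L, pad = 0L)$y
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

## ---- parameter construction ----

res_init <- function(C_in, C_out, De) {
  p <- list(gn1_gamma = rep(1, C_in), gn1_beta = numeric(C_in),
            conv1 = conv1d_init(C_in, C_out, 3L),
            tproj = linear_init(De, C_out),
            gn2_gamma = rep(1, C_out), gn2_beta = numeric(C_out),
            conv2 = conv1d_init(C_out, C_out, 3L, gain = 0.2))
  if (C_in != C_out) p$skip <- conv1d_init(C_in, C_out, 1L)
  p
}

#' Build a 1D U-Net noise model
#'
#' Initializes all network parameters (seeded). The returned model is a
#' plain list of parameter arrays plus its configuration; it is consumed
#' by [train_diffusion()] and the sampling/restoration functions.
#'
#' @param config A [unet_config()].
#' @param seed RNG seed for weight initialization.
#' @return An object of class `unet_model`.
#' @export
build_unet <- function(config, seed = 1) {
  stopifnot(inherits(config, "unet_config"))
  cfg <- config
  De <- cfg$time_embed_dim
  nl <- cfg$n_levels
  ch <- cfg$base_channels * cfg$channel_mults
  params <- with_seed(seed, {
    p <- list(tmlp1 = linear_init(De, De), tmlp2 = linear_init(De, De))
    if (!is.null(cfg$n_classes)) {
      # label embeddings start well-separated so the class signal is
      # visible to the blocks from the first epochs
      p$label_emb <- matrix(stats::rnorm(De * cfg$n_classes, 0, 0.5),
                            De, cfg$n_classes)
    }
    # in signal mode the conditioning channels are concatenated to the
    # input and consumed directly by the stem convolution, which is the
    # layer that refines the amalgamated state+condition input
    stem_in <- cfg$in_channels +
      if (!is.null(cfg$cond_channels)) cfg$cond_channels else 0L
    p$stem <- conv1d_init(stem_in, ch[1], 3L)
    p$enc <- vector("list", nl)
    for (i in seq_len(nl)) {
      cin <- if (i == 1L) ch[1] else ch[i - 1L]
      lev <- list(res = vector("list", cfg$n_res_blocks))
      for (r in seq_len(cfg$n_res_blocks)) {
        lev$res[[r]] <- res_init(if (r == 1L) cin else ch[i], ch[i], De)
      }
      if (cfg$attention[i]) lev$attn <- attn_init(ch[i])
      if (i < nl) lev$down <- conv1d_init(ch[i], ch[i], 3L)
      p$enc[[i]] <- lev
    }
    p$mid <- list(res1 = res_init(ch[nl], ch[nl], De),
                  attn = attn_init(ch[nl]),
                  res2 = res_init(ch[nl], ch[nl], De))
    p$dec <- vector("list", nl)
    for (i in seq_len(nl)) {
      cout <- if (i == 1L) ch[1] else ch[i - 1L]
      lev <- list(res = vector("list", cfg$n_res_blocks))
      for (r in seq_len(cfg$n_res_blocks)) {
        cin_r <- if (r == 1L) 2L * ch[i] else cout
        lev$res[[r]] <- res_init(cin_r, cout, De)
      }
      if (cfg$attention[i]) lev$attn <- attn_init(cout)
      if (i > 1L) lev$up <- conv1d_init(cout, cout, 3L)
      p$dec[[i]] <- lev
    }
    p$head_gamma <- rep(1, ch[1])
    p$head_beta <- numeric(ch[1])
    p$head_conv <- conv1d_init(ch[1], 2L * cfg$in_channels, 3L, zero = TRUE)
    p
  })
  structure(list(params = params, cfg = cfg), class = "unet_model")
}

#' Total parameter count of a U-Net model
#' @param model A `unet_model`.
#' @return Integer number of scalar parameters.
#' @export
n_params <- function(model) {
  cnt <- function(x) if (is.list(x)) sum(vapply(x, cnt, numeric(1))) else length(x)
  cnt(model$params)
}

## ---- residual block forward/backward ----

res_fw <- function(x, temb_s, p) {
  gn1 <- groupnorm_fw(x, p$gn1_gamma, p$gn1_beta)
  a1 <- silu_fw(gn1$y)
  c1 <- conv1d_fw(a1$y, p$conv1$W, p$conv1$b, 1L, 1L)
  pr <- linear_fw(temb_s, p$tproj$W, p$tproj$b)       # (C_out, B)
  dmy <- dim(c1$y)
  h <- c1$y + aperm(array(pr$y, c(dmy[1], dmy[3], dmy[2])), c(1, 3, 2))
  gn2 <- groupnorm_fw(h, p$gn2_gamma, p$gn2_beta)
  a2 <- silu_fw(gn2$y)
  c2 <- conv1d_fw(a2$y, p$conv2$W, p$conv2$b, 1L, 1L)
  if (!is.null(p$skip)) {
    sk <- conv1d_fw(x, p$skip$W, p$skip$b, 1L, 0L)
    y <- c2$y + sk$y
    skc <- sk$cache
  } else {
    y <- c2$y + x
    skc <- NULL
  }
  list(y = y, cache = list(gn1 = gn1$cache, a1 = a1$cache, c1 = c1$cache,
                           pr = pr$cache, gn2 = gn2$cache, a2 = a2$cache,
                           c2 = c2$cache, sk = skc))
}

res_bw <- function(dy, cache) {
  c2b <- conv1d_bw(dy, cache$c2)
  da2 <- silu_bw(c2b$dx, cache$a2)
  gn2b <- groupnorm_bw(da2, cache$gn2)
  dh <- gn2b$dx
  dprm <- colSums(aperm(dh, c(2, 1, 3)))               # (C_out, B)
  prb <- linear_bw(dprm, cache$pr)
  c1b <- conv1d_bw(dh, cache$c1)
  da1 <- silu_bw(c1b$dx, cache$a1)
  gn1b <- groupnorm_bw(da1, cache$gn1)
  dx <- gn1b$dx
  grads <- list(gn1_gamma = gn1b$dgamma, gn1_beta = gn1b$dbeta,
                conv1 = list(W = c1b$dW, b = c1b$db),
                tproj = list(W = prb$dW, b = prb$db),
                gn2_gamma = gn2b$dgamma, gn2_beta = gn2b$dbeta,
                conv2 = list(W = c2b$dW, b = c2b$db))
  if (!is.null(cache$sk)) {
    skb <- conv1d_bw(dy, cache$sk)
    dx <- dx + skb$dx
    grads$skip <- list(W = skb$dW, b = skb$db)
  } else {
    dx <- dx + dy
  }
  list(dx = dx, dtemb_s = prb$dx, grads = grads)
}

## ---- full network forward/backward ----

unet_forward <- function(model, x, tvec, label = NULL, cond = NULL) {
  cfg <- model$cfg
  p <- model$params
  nl <- cfg$n_levels
  B <- dim(x)[3]
  ca <- list()

  sin_emb <- embed_timestep(tvec, cfg$time_embed_dim)
  l1 <- linear_fw(sin_emb, p$tmlp1$W, p$tmlp1$b)
  a0 <- silu_fw(l1$y)
  l2 <- linear_fw(a0$y, p$tmlp2$W, p$tmlp2$b)
  temb <- l2$y
  if (!is.null(cfg$n_classes)) {
    if (is.null(label)) stopf("model is label-conditional: `label` required")
    temb <- temb + inject_label(as.integer(label), cfg$n_classes, p$label_emb)
  } else if (!is.null(label)) {
    stopf("model is not label-conditional")
  }
  ts <- silu_fw(temb)
  temb_s <- ts$y
  ca$emb <- list(l1 = l1$cache, a0 = a0$cache, l2 = l2$cache, ts = ts$cache,
                 label = if (!is.null(cfg$n_classes)) as.integer(label))

  h <- x
  if (!is.null(cfg$cond_channels) && cfg$cond_channels > 0) {
    if (is.null(cond)) stopf("model is signal-conditional: `cond` required")
    if (!identical(dim(cond)[2:3], dim(x)[2:3])) {
      stopf("conditioning signal dimensions do not match the input")
    }
    h <- cat_channels(h, cond)
  } else if (!is.null(cond)) {
    stopf("model is not signal-conditional")
  }

  st <- conv1d_fw(h, p$stem$W, p$stem$b, 1L, 1L)
  h <- st$y
  ca$stem <- st$cache

  skips <- vector("list", nl)
  ca$enc <- vector("list", nl)
  for (i in seq_len(nl)) {
    lev <- list(res = vector("list", cfg$n_res_blocks))
    for (r in seq_len(cfg$n_res_blocks)) {
      rb <- res_fw(h, temb_s, p$enc[[i]]$res[[r]])
      h <- rb$y
      lev$res[[r]] <- rb$cache
    }
    if (cfg$attention[i]) {
      ab <- attn_fw(h, p$enc[[i]]$attn)
      h <- ab$y
      lev$attn <- ab$cache
    }
    skips[[i]] <- h
    if (i < nl) {
      dn <- conv1d_fw(h, p$enc[[i]]$down$W, p$enc[[i]]$down$b, 2L, 1L)
      h <- dn$y
      lev$down <- dn$cache
    }
    ca$enc[[i]] <- lev
  }

  m1 <- res_fw(h, temb_s, p$mid$res1)
  ma <- attn_fw(m1$y, p$mid$attn)
  m2 <- res_fw(ma$y, temb_s, p$mid$res2)
  h <- m2$y
  ca$mid <- list(r1 = m1$cache, at = ma$cache, r2 = m2$cache)

  ca$dec <- vector("list", nl)
  for (i in rev(seq_len(nl))) {
    lev <- list()
    hcat <- cat_channels(h, skips[[i]])
    lev$nskip <- dim(h)[1]
    lev$res <- vector("list", cfg$n_res_blocks)
    h <- hcat
    for (r in seq_len(cfg$n_res_blocks)) {
      rb <- res_fw(h, temb_s, p$dec[[i]]$res[[r]])
      h <- rb$y
      lev$res[[r]] <- rb$cache
    }
    if (cfg$attention[i]) {
      ab <- attn_fw(h, p$dec[[i]]$attn)
      h <- ab$y
      lev$attn <- ab$cache
    }
    if (i > 1L) {
      up <- upsample2_fw(h)
      uc <- conv1d_fw(up$y, p$dec[[i]]$up$W, p$dec[[i]]$up$b, 1L, 1L)
      h <- uc$y
      lev$up <- list(us = up$cache, conv = uc$cache)
    }
    ca$dec[[i]] <- lev
  }

  hg <- groupnorm_fw(h, p$head_gamma, p$head_beta)
  hs <- silu_fw(hg$y)
  hc2 <- conv1d_fw(hs$y, p$head_conv$W, p$head_conv$b, 1L, 1L)
  ca$head <- list(gn = hg$cache, si = hs$cache, conv = hc2$cache)

  Cin <- cfg$in_channels
  eps <- hc2$y[seq_len(Cin), , , drop = FALSE]
  vraw <- hc2$y[Cin + seq_len(Cin), , , drop = FALSE]
  v <- sigmoid(vraw)
  list(eps = eps, v = v, cache = c(ca, list(v = v, B = B)))
}

unet_backward <- function(model, cache, d_eps, d_v) {
  cfg <- model$cfg
  p <- model$params
  nl <- cfg$n_levels
  Cin <- cfg$in_channels

  dvraw <- d_v * cache$v * (1 - cache$v)
  dhead <- cat_channels(d_eps, dvraw)
  hcb <- conv1d_bw(dhead, cache$head$conv)
  dsi <- silu_bw(hcb$dx, cache$head$si)
  gnb <- groupnorm_bw(dsi, cache$head$gn)
  dh <- gnb$dx

  g <- list(tmlp1 = NULL, tmlp2 = NULL)       # filled at the end
  dtemb_s <- 0

  g$dec <- vector("list", nl)
  dskips <- vector("list", nl)
  for (i in seq_len(nl)) {                    # reverse of the decoder loop
    lev <- cache$dec[[i]]
    gl <- list()
    if (i > 1L) {
      ub <- conv1d_bw(dh, lev$up$conv)
      gl$up <- list(W = ub$dW, b = ub$db)
      dh <- upsample2_bw(ub$dx, lev$up$us)
    }
    if (cfg$attention[i]) {
      ab <- attn_bw(dh, lev$attn)
      gl$attn <- ab$grads
      dh <- ab$dx
    }
    gl$res <- vector("list", cfg$n_res_blocks)
    for (r in rev(seq_len(cfg$n_res_blocks))) {
      rb <- res_bw(dh, lev$res[[r]])
      dh <- rb$dx
      dtemb_s <- dtemb_s + rb$dtemb_s
      gl$res[[r]] <- rb$grads
    }
    ns <- lev$nskip
    dskips[[i]] <- dh[ns + seq_len(dim(dh)[1] - ns), , , drop = FALSE]
    dh <- dh[seq_len(ns), , , drop = FALSE]
    g$dec[[i]] <- gl
  }

  m2 <- res_bw(dh, cache$mid$r2); dtemb_s <- dtemb_s + m2$dtemb_s
  ma <- attn_bw(m2$dx, cache$mid$at)
  m1 <- res_bw(ma$dx, cache$mid$r1); dtemb_s <- dtemb_s + m1$dtemb_s
  g$mid <- list(res1 = m1$grads, attn = ma$grads, res2 = m2$grads)
  dh <- m1$dx

  g$enc <- vector("list", nl)
  for (i in rev(seq_len(nl))) {
    lev <- cache$enc[[i]]
    gl <- list()
    if (i < nl) {
      db <- conv1d_bw(dh, lev$down)
      gl$down <- list(W = db$dW, b = db$db)
      dh <- db$dx
    }
    # the stream entering down (or the bottleneck, at the deepest level)
    # is the same tensor pushed as the skip, so both gradients add here
    dh <- dh + dskips[[i]]
    if (cfg$attention[i]) {
      ab <- attn_bw(dh, lev$attn)
      gl$attn <- ab$grads
      dh <- ab$dx
    }
    gl$res <- vector("list", cfg$n_res_blocks)
    for (r in rev(seq_len(cfg$n_res_blocks))) {
      rb <- res_bw(dh, lev$res[[r]])
      dh <- rb$dx
      dtemb_s <- dtemb_s + rb$dtemb_s
      gl$res[[r]] <- rb$grads
    }
    g$enc[[i]] <- gl
  }

  stb <- conv1d_bw(dh, cache$stem)
  g$stem <- list(W = stb$dW, b = stb$db)

  # embedding pathway
  dtemb <- silu_bw(dtemb_s, cache$emb$ts)
  if (!is.null(cfg$n_classes)) {
    dle <- matrix(0, cfg$time_embed_dim, cfg$n_classes)
    lab <- cache$emb$label + 1L
    for (b in seq_along(lab)) dle[, lab[b]] <- dle[, lab[b]] + dtemb[, b]
    g$label_emb <- dle
  }
  l2b <- linear_bw(dtemb, cache$emb$l2)
  da0 <- silu_bw(l2b$dx, cache$emb$a0)
  l1b <- linear_bw(da0, cache$emb$l1)
  g$tmlp1 <- list(W = l1b$dW, b = l1b$db)
  g$tmlp2 <- list(W = l2b$dW, b = l2b$db)

  # return with the exact same element order as model$params
  out <- list(tmlp1 = g$tmlp1, tmlp2 = g$tmlp2)
  if (!is.null(cfg$n_classes)) out$label_emb <- g$label_emb
  out$stem <- g$stem
  out$enc <- g$enc
  out$mid <- g$mid
  out$dec <- g$dec
  out$head_gamma <- gnb$dgamma
  out$head_beta <- gnb$dbeta
  out$head_conv <- list(W = hcb$dW, b = hcb$db)
  out
}
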