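## Minimal neural-network primitives used by the 1D U-Net, the recurrent
## discriminative classifier, and the 1D-CNN classifier.
##
## Tensor layout convention throughout: a batch of feature maps is a 3D
## array of dimension (channels C, length L, batch B). Convolutions are
## evaluated as im2col gathers followed by one BLAS matrix multiply; every
## op has a matching hand-derived backward pass. Correctness of the
## gradients is pinned by numerical gradient-check tests.

.idx_cache <- new.env(parent = emptyenv())

conv1d_indices <- function(C, L, B, k, stride, pad) {
  key <- paste(C, L, B, k, stride, pad, sep = ".")
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  Lp <- L + 2L * pad
  Lout <- (Lp - k) %/% stride + 1L
  c_vec <- rep(seq_len(C), k)
  j_vec <- rep(seq_len(k), each = C)
  rowterm <- c_vec + C * (j_vec - 1L)              # C*k values
  o_vec <- rep(seq_len(Lout), B)
  b_vec <- rep(seq_len(B), each = Lout)
  colterm <- C * stride * (o_vec - 1L) + C * Lp * (b_vec - 1L)
  idx <- outer(rowterm, colterm, "+")
  storage.mode(idx) <- "integer"
  out <- list(idx = idx, Lout = Lout, Lp = Lp)
  .idx_cache[[key]] <- out
  out
}

## W: (C_out, C_in * k) with columns ordered channel-fastest within tap;
## b: length C_out. x: (C_in, L, B). Returns y (C_out, Lout, B) + cache.
conv1d_fw <- function(x, W, b, stride = 1L, pad = 1L) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  k <- ncol(W) %/% C
  ii <- conv1d_indices(C, L, B, k, stride, pad)
  if (pad > 0L) {
    xp <- array(0, c(C, ii$Lp, B))
    xp[, (pad + 1L):(pad + L), ] <- x
  } else xp <- x
  Xcol <- matrix(xp[ii$idx], nrow = C * k)
  y <- W %*% Xcol + b
  list(y = array(y, c(nrow(W), ii$Lout, B)),
       cache = list(Xcol = Xcol, ii = ii, dims = d, W = W,
                    stride = stride, pad = pad, k = k))
}

conv1d_bw <- function(dy, cache) {
  d <- cache$dims; C <- d[1]; L <- d[2]; B <- d[3]
  ii <- cache$ii
  k <- cache$k; s <- cache$stride
  dY <- matrix(dy, nrow = dim(dy)[1])
  dW <- tcrossprod(dY, cache$Xcol)
  db <- rowSums(dY)
  dXcol <- crossprod(cache$W, dY)                   # (C*k, Lout*B)
  # col2im as k strided adds: tap j of output position o maps to padded
  # position (o-1)*s + j, a regular slice for fixed j
  dxp <- array(0, c(C, ii$Lp, B))
  pos0 <- (seq_len(ii$Lout) - 1L) * s
  for (j in seq_len(k)) {
    blk <- array(dXcol[(j - 1L) * C + seq_len(C), ], c(C, ii$Lout, B))
    tgt <- pos0 + j
    dxp[, tgt, ] <- dxp[, tgt, , drop = FALSE] + blk
  }
  dx <- if (cache$pad > 0L) {
    dxp[, (cache$pad + 1L):(cache$pad + L), , drop = FALSE]
  } else dxp
  list(dx = dx, dW = dW, db = db)
}

conv1d_init <- function(C_in, C_out, k, gain = 1, zero = FALSE) {
  if (zero) {
    W <- matrix(0, C_out, C_in * k)
  } else {
    sd <- gain * sqrt(2 / (C_in * k))
    W <- matrix(stats::rnorm(C_out * C_in * k, 0, sd), C_out, C_in * k)
  }
  list(W = W, b = numeric(C_out))
}

linear_fw <- function(x, W, b) {
  list(y = W %*% x + b, cache = list(x = x, W = W))
}

linear_bw <- function(dy, cache) {
  list(dx = crossprod(cache$W, dy),
       dW = tcrossprod(dy, cache$x),
       db = rowSums(dy))
}

linear_init <- function(d_in, d_out, zero = FALSE) {
  if (zero) W <- matrix(0, d_out, d_in)
  else W <- matrix(stats::rnorm(d_out * d_in, 0, sqrt(2 / d_in)), d_out, d_in)
  list(W = W, b = numeric(d_out))
}

silu_fw <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(y = x * s, cache = list(x = x, s = s))
}

silu_bw <- function(dy, cache) {
  s <- cache$s
  dy * (s * (1 + cache$x * (1 - s)))
}

relu_fw <- function(x) list(y = pmax(x, 0), cache = list(pos = x > 0))
relu_bw <- function(dy, cache) dy * cache$pos

sigmoid <- function(x) 1 / (1 + exp(-x))

## Group normalization over (channels-in-group x length) per sample, with
## per-channel affine parameters. Channels must be divisible by `groups`.
gn_groups <- function(C) {
  for (g in c(8L, 4L, 2L, 1L)) if (C %% g == 0L) return(g)
  1L
}

groupnorm_fw <- function(x, gamma, beta, groups = gn_groups(dim(x)[1]),
                         eps = 1e-5) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  Cg <- C %/% groups
  xg <- array(x, c(Cg, groups, L, B))
  xp <- aperm(xg, c(1, 3, 2, 4))              # (Cg, L, G, B)
  xm <- matrix(xp, nrow = Cg * L)             # cols = (g, b)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = Cg * L)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat_m <- xc * rep(istd, each = Cg * L)
  xhat <- array(aperm(array(xhat_m, c(Cg, L, groups, B)), c(1, 3, 2, 4)), d)
  y <- xhat * gamma + beta                     # recycle along channel axis
  list(y = y, cache = list(xhat = xhat, istd = istd, gamma = gamma,
                           dims = d, groups = groups))
}

groupnorm_bw <- function(dy, cache) {
  d <- cache$dims; C <- d[1]; L <- d[2]; B <- d[3]
  groups <- cache$groups; Cg <- C %/% groups
  xhat <- cache$xhat
  dgamma <- rowSums(matrix(aperm(dy * xhat, c(1, 2, 3)), nrow = C))
  dbeta <- rowSums(matrix(dy, nrow = C))
  dxhat <- dy * cache$gamma
  to_m <- function(a) matrix(aperm(array(a, c(Cg, groups, L, B)),
                                   c(1, 3, 2, 4)), nrow = Cg * L)
  dxh_m <- to_m(dxhat)
  xh_m <- to_m(xhat)
  n <- Cg * L
  m1 <- colMeans(dxh_m)
  m2 <- colMeans(dxh_m * xh_m)
  dx_m <- (dxh_m - rep(m1, each = n) - xh_m * rep(m2, each = n)) *
    rep(cache$istd, each = n)
  dx <- array(aperm(array(dx_m, c(Cg, L, groups, B)), c(1, 3, 2, 4)), d)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## Single-head self-attention over the time axis with residual output:
## y = x + Wo (V softmax(Q^T K / sqrt(C))^T), Q/K/V from a group-normalized
## copy of x. Evaluated per sample; lengths are small where attention sits.
attn_init <- function(C) {
  sd <- sqrt(1 / C)
  list(gamma = rep(1, C), beta = numeric(C),
       Wq = matrix(stats::rnorm(C * C, 0, sd), C, C),
       Wk = matrix(stats::rnorm(C * C, 0, sd), C, C),
       Wv = matrix(stats::rnorm(C * C, 0, sd), C, C),
       Wo = matrix(0, C, C), bo = numeric(C))
}

attn_fw <- function(x, p) {
  d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
  gn <- groupnorm_fw(x, p$gamma, p$beta)
  h <- gn$y
  sc <- 1 / sqrt(C)
  per <- vector("list", B)
  y <- x
  for (b in seq_len(B)) {
    hm <- matrix(h[, , b], C, L)
    q <- p$Wq %*% hm; kk <- p$Wk %*% hm; v <- p$Wv %*% hm
    s <- crossprod(q, kk) * sc                 # (L, L), s[i,j] = q_i . k_j
    s <- s - apply(s, 1, max)
    e <- exp(s)
    A <- e / rowSums(e)
    o <- v %*% t(A)                            # o_i = sum_j A[i,j] v_j
    out <- p$Wo %*% o + p$bo
    y[, , b] <- y[, , b] + out
    per[[b]] <- list(hm = hm, q = q, k = kk, v = v, A = A, o = o)
  }
  list(y = y, cache = list(gn = gn$cache, per = per, dims = d, p = p, sc = sc))
}

attn_bw <- function(dy, cache) {
  d <- cache$dims; C <- d[1]; L <- d[2]; B <- d[3]
  p <- cache$p
  dWq <- matrix(0, C, C); dWk <- matrix(0, C, C)
  dWv <- matrix(0, C, C); dWo <- matrix(0, C, C)
  dbo <- numeric(C)
  dh <- array(0, d)
  for (b in seq_len(B)) {
    pc <- cache$per[[b]]
    dout <- matrix(dy[, , b], C, L)
    dWo <- dWo + tcrossprod(dout, pc$o)
    dbo <- dbo + rowSums(dout)
    do_ <- crossprod(p$Wo, dout)               # (C, L)
    dA <- crossprod(pc$v, do_)                 # dA[j,i] = v_j . do_i -> (L,L) transposed
    dA <- t(dA)                                # dA[i,j]
    dv <- do_ %*% pc$A                         # dv_j = sum_i A[i,j] do_i
    # softmax backward along rows
    dS <- pc$A * (dA - rowSums(pc$A * dA))
    dq <- pc$k %*% t(dS) * cache$sc            # dq_i = sc * sum_j dS[i,j] k_j
    dk <- pc$q %*% dS * cache$sc               # dk_j = sc * sum_i dS[i,j] q_i
    dWq <- dWq + tcrossprod(dq, pc$hm)
    dWk <- dWk + tcrossprod(dk, pc$hm)
    dWv <- dWv + tcrossprod(dv, pc$hm)
    dh[, , b] <- crossprod(p$Wq, dq) + crossprod(p$Wk, dk) +
      crossprod(p$Wv, dv)
  }
  gnb <- groupnorm_bw(dh, cache$gn)
  list(dx = dy + gnb$dx,
       grads = list(gamma = gnb$dgamma, beta = gnb$dbeta,
                    Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo, bo = dbo))
}

## nearest-neighbour x2 upsampling along the time axis
upsample2_fw <- function(x) {
  d <- dim(x)
  y <- array(0, c(d[1], 2L * d[2], d[3]))
  y[, seq(1L, 2L * d[2], by = 2L), ] <- x
  y[, seq(2L, 2L * d[2], by = 2L), ] <- x
  list(y = y, cache = list(L = d[2]))
}

upsample2_bw <- function(dy, cache) {
  L <- cache$L
  dy[, seq(1L, 2L * L, by = 2L), , drop = FALSE] +
    dy[, seq(2L, 2L * L, by = 2L), , drop = FALSE]
}

## max pooling (width 2, stride 2) for the CNN classifier
maxpool2_fw <- function(x) {
  d <- dim(x); L2 <- d[2] %/% 2L
  a <- x[, seq(1L, 2L * L2, by = 2L), , drop = FALSE]
  b <- x[, seq(2L, 2L * L2, by = 2L), , drop = FALSE]
  amax <- a >= b
  list(y = ifelse(amax, a, b), cache = list(amax = amax, d = d, L2 = L2))
}

maxpool2_bw <- function(dy, cache) {
  d <- cache$d; L2 <- cache$L2
  dx <- array(0, d)
  dx[, seq(1L, 2L * L2, by = 2L), ] <- dy * cache$amax
  dx[, seq(2L, 2L * L2, by = 2L), ] <- dy * !cache$amax
  dx
}

## ---- Adam over arbitrarily nested lists of numeric arrays ----

nested_map <- function(f, ...) {
  xs <- list(...)
  if (is.list(xs[[1]])) {
    nm <- names(xs[[1]])
    keys <- if (!is.null(nm) && all(nzchar(nm))) nm else seq_along(xs[[1]])
    out <- lapply(keys, function(i) {
      do.call(nested_map, c(list(f), lapply(xs, `[[`, i)))
    })
    names(out) <- nm
    out
  } else {
    do.call(f, xs)
  }
}

nested_zeros <- function(params) nested_map(function(p) p * 0, params)

adam_init <- function(params) {
  list(m = nested_zeros(params), v = nested_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nested_map(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- nested_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- nested_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

nested_add <- function(a, b) nested_map(`+`, a, b)

## global grad-norm clip to keep small-batch training stable
nested_sumsq <- function(g) {
  if (is.list(g)) sum(vapply(g, nested_sumsq, numeric(1))) else sum(g * g)
}

clip_grads <- function(grads, max_norm = 1) {
  nrm <- sqrt(nested_sumsq(grads))
  if (is.finite(nrm) && nrm > max_norm) {
    grads <- nested_map(function(g) g * (max_norm / nrm), grads)
  }
  grads
}
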