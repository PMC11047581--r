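## Stacked LSTM binary classifier used by the discriminative score:
## 2 layers, hidden size 64, final hidden state -> logistic output,
## binary cross-entropy loss, full backpropagation through time.

lstm_layer_init <- function(d_in, H) {
  sd <- sqrt(1 / (d_in + H))
  W <- matrix(stats::rnorm(4 * H * (d_in + H), 0, sd), 4 * H, d_in + H)
  b <- numeric(4 * H)
  b[H + seq_len(H)] <- 1            # forget-gate bias
  list(W = W, b = b)
}

lstm_init <- function(d_in, hidden = 64, layers = 2, seed = 1) {
  with_seed(seed, {
    p <- list(layers = lapply(seq_len(layers), function(l) {
      lstm_layer_init(if (l == 1L) d_in else hidden, hidden)
    }))
    p$out <- linear_init(hidden, 1)
    p
  })
}

## x: (C, L, B). Returns probability vector (length B) + cache for BPTT.
lstm_forward <- function(params, x) {
  d <- dim(x); L <- d[2]; B <- d[3]
  nl <- length(params$layers)
  H <- length(params$layers[[1]]$b) %/% 4L
  hs <- lapply(seq_len(nl), function(l) matrix(0, H, B))
  cs <- lapply(seq_len(nl), function(l) matrix(0, H, B))
  steps <- vector("list", L)
  for (t in seq_len(L)) {
    xt <- matrix(x[, t, ], d[1], B)
    st <- vector("list", nl)
    for (l in seq_len(nl)) {
      p <- params$layers[[l]]
      xin <- rbind(xt, hs[[l]])
      z <- p$W %*% xin + p$b
      i <- sigmoid(z[seq_len(H), , drop = FALSE])
      f <- sigmoid(z[H + seq_len(H), , drop = FALSE])
      g <- tanh(z[2L * H + seq_len(H), , drop = FALSE])
      o <- sigmoid(z[3L * H + seq_len(H), , drop = FALSE])
      c_new <- f * cs[[l]] + i * g
      tc <- tanh(c_new)
      st[[l]] <- list(xin = xin, c_prev = cs[[l]],
                      i = i, f = f, g = g, o = o, tc = tc)
      hs[[l]] <- o * tc
      cs[[l]] <- c_new
      xt <- hs[[l]]
    }
    steps[[t]] <- st
  }
  lo <- linear_fw(hs[[nl]], params$out$W, params$out$b)
  prob <- as.vector(sigmoid(lo$y))
  list(prob = prob,
       cache = list(steps = steps, lo = lo$cache, H = H, nl = nl,
                    L = L, B = B, d_in = d[1]))
}

## dlogit: gradient wrt the pre-sigmoid output logit (length B)
lstm_backward <- function(params, cache, dlogit) {
  H <- cache$H; nl <- cache$nl; L <- cache$L; B <- cache$B
  lob <- linear_bw(matrix(dlogit, 1, B), cache$lo)
  g <- list(layers = lapply(seq_len(nl), function(l) {
    list(W = params$layers[[l]]$W * 0, b = params$layers[[l]]$b * 0)
  }), out = list(W = lob$dW, b = lob$db))
  dh_next <- lapply(seq_len(nl), function(l) matrix(0, H, B))
  dc_next <- lapply(seq_len(nl), function(l) matrix(0, H, B))
  dh_next[[nl]] <- matrix(lob$dx, H, B)      # head reads h_L of top layer
  for (t in rev(seq_len(L))) {
    dfrom_above <- NULL
    for (l in rev(seq_len(nl))) {
      st <- cache$steps[[t]][[l]]
      p <- params$layers[[l]]
      dh <- dh_next[[l]] + (dfrom_above %||% 0)
      do_ <- dh * st$tc
      dc <- dc_next[[l]] + dh * st$o * (1 - st$tc^2)
      di <- dc * st$g
      df <- dc * st$c_prev
      dg <- dc * st$i
      dz <- rbind(di * st$i * (1 - st$i),
                  df * st$f * (1 - st$f),
                  dg * (1 - st$g^2),
                  do_ * st$o * (1 - st$o))
      g$layers[[l]]$W <- g$layers[[l]]$W + tcrossprod(dz, st$xin)
      g$layers[[l]]$b <- g$layers[[l]]$b + rowSums(dz)
      dxh <- crossprod(p$W, dz)
      d_in_l <- nrow(st$xin) - H
      dfrom_above <- dxh[seq_len(d_in_l), , drop = FALSE]   # to layer below
      dh_next[[l]] <- dxh[d_in_l + seq_len(H), , drop = FALSE]
      dc_next[[l]] <- dc * st$f
    }
  }
  g
}

## Train the binary classifier with Adam + early stopping on held-out BCE.
## x_*: (C, L, B) arrays, y_*: 0/1 vectors. Returns params + history.
lstm_train <- function(x_tr, y_tr, x_va, y_va, hidden = 64, layers = 2,
                       epochs = 50, patience = 5, lr = 2e-3,
                       batch_size = 32, seed = 1) {
  params <- lstm_init(dim(x_tr)[1], hidden, layers,
                      seed = derive_seed(seed, 5L))
  opt <- adam_init(params)
  n <- dim(x_tr)[3]
  best <- list(val = Inf, params = params)
  bad <- 0L
  with_seed(derive_seed(seed, 7L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (b0 in seq(1L, n, by = batch_size)) {
        bi <- ord[b0:min(b0 + batch_size - 1L, n)]
        fw <- lstm_forward(params, x_tr[, , bi, drop = FALSE])
        pr <- pmin(pmax(fw$prob, 1e-7), 1 - 1e-7)
        dlogit <- (pr - y_tr[bi]) / length(bi)   # BCE on logits
        gr <- clip_grads(lstm_backward(params, fw$cache, dlogit), 5)
        st <- adam_step(params, gr, opt, lr)
        params <- st$params; opt <- st$state
      }
      fv <- lstm_forward(params, x_va)
      pv <- pmin(pmax(fv$prob, 1e-7), 1 - 1e-7)
      val <- -mean(y_va * log(pv) + (1 - y_va) * log(1 - pv))
      if (val < best$val - 1e-6) {
        best <- list(val = val, params = params)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
  })
  best
}
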