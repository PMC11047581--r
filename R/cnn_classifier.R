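## Small fixed 1D-CNN classifier: two conv/pool blocks and a dense head.
## Used as the downstream model in the class-imbalance experiment and as
## the oracle classifier in label-conditioning checks. Architecture is
## pinned so that before/after-augmentation comparisons are controlled.

#' Classifier configuration
#'
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param channels Feature channels of the two convolution blocks.
#' @param kernel Convolution kernel width (odd).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(epochs = 25, lr = 2e-3, batch_size = 32,
                              channels = c(16, 32), kernel = 5) {
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 channels = as.integer(channels), kernel = as.integer(kernel)),
            class = "classifier_config")
}

cnn_init <- function(C_in, L, n_classes, config, seed = 1) {
  ch <- config$channels; k <- config$kernel
  L_out <- (L %/% 2L) %/% 2L
  with_seed(seed, {
    list(conv1 = conv1d_init(C_in, ch[1], k),
         conv2 = conv1d_init(ch[1], ch[2], k),
         fc = linear_init(ch[2] * L_out, n_classes))
  })
}

cnn_forward <- function(params, x, k) {
  pad <- (k - 1L) %/% 2L
  c1 <- conv1d_fw(x, params$conv1$W, params$conv1$b, 1L, pad)
  r1 <- relu_fw(c1$y)
  p1 <- maxpool2_fw(r1$y)
  c2 <- conv1d_fw(p1$y, params$conv2$W, params$conv2$b, 1L, pad)
  r2 <- relu_fw(c2$y)
  p2 <- maxpool2_fw(r2$y)
  d <- dim(p2$y)
  fl <- matrix(p2$y, d[1] * d[2], d[3])
  lo <- linear_fw(fl, params$fc$W, params$fc$b)    # (n_classes, B)
  z <- lo$y
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  ez <- exp(z)
  probs <- ez / rep(colSums(ez), each = nrow(z))
  list(probs = probs,
       cache = list(c1 = c1$cache, r1 = r1$cache, p1 = p1$cache,
                    c2 = c2$cache, r2 = r2$cache, p2 = p2$cache,
                    lo = lo$cache, dflat = d, probs = probs))
}

## y: 0-based labels. Cross-entropy gradients through softmax.
cnn_backward <- function(params, cache, y) {
  probs <- cache$probs
  B <- ncol(probs)
  dz <- probs
  dz[cbind(y + 1L, seq_len(B))] <- dz[cbind(y + 1L, seq_len(B))] - 1
  dz <- dz / B
  lob <- linear_bw(dz, cache$lo)
  d <- cache$dflat
  dp2 <- array(lob$dx, d)
  dr2 <- maxpool2_bw(dp2, cache$p2)
  dc2 <- relu_bw(dr2, cache$r2)
  c2b <- conv1d_bw(dc2, cache$c2)
  dp1 <- c2b$dx
  dr1 <- maxpool2_bw(dp1, cache$p1)
  dc1 <- relu_bw(dr1, cache$r1)
  c1b <- conv1d_bw(dc1, cache$c1)
  list(conv1 = list(W = c1b$dW, b = c1b$db),
       conv2 = list(W = c2b$dW, b = c2b$db),
       fc = list(W = lob$dW, b = lob$db))
}

#' Train the fixed 1D-CNN classifier
#'
#' @param data Labelled [signal_set()].
#' @param config A [classifier_config()].
#' @param seed Seed for initialization and batching.
#' @return A `cnn_classifier` with weights, normalization, and label set.
#' @export
train_cnn_classifier <- function(data, config = classifier_config(),
                                 seed = 1) {
  stopifnot(inherits(data, "signal_set"))
  if (is.null(data$labels)) stopf("labelled data required")
  d <- dim(data$values)
  label_set <- sort(unique(data$labels))
  y <- match(data$labels, label_set) - 1L
  norm <- fit_norm(data$values)
  x <- apply_norm(ss_to_clb(data$values), norm)
  params <- cnn_init(d[2], d[3], length(label_set), config,
                     seed = derive_seed(seed, 3L))
  opt <- adam_init(params)
  with_seed(derive_seed(seed, 17L), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(d[1])
      for (b0 in seq(1L, d[1], by = config$batch_size)) {
        bi <- ord[b0:min(b0 + config$batch_size - 1L, d[1])]
        fw <- cnn_forward(params, x[, , bi, drop = FALSE], config$kernel)
        gr <- clip_grads(cnn_backward(params, fw$cache, y[bi]), 5)
        st <- adam_step(params, gr, opt, config$lr)
        params <- st$params; opt <- st$state
      }
    }
  })
  structure(list(params = params, config = config, norm = norm,
                 label_set = label_set, n_channels = d[2], length = d[3]),
            class = "cnn_classifier")
}

#' Predict class labels with a trained CNN classifier
#'
#' @param object A `cnn_classifier`.
#' @param newdata A [signal_set()].
#' @param ... Unused.
#' @return Integer vector of predicted labels (original label values).
#' @export
predict.cnn_classifier <- function(object, newdata, ...) {
  x <- apply_norm(ss_to_clb(newdata$values), object$norm)
  probs <- cnn_forward(object$params, x, object$config$kernel)$probs
  object$label_set[max.col(t(probs), ties.method = "first")]
}
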