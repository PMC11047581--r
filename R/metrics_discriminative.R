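#' Discriminative score between a real and a synthetic set
#'
#' A post-hoc two-sample test phrased as classification: real sequences
#' are labelled 1 and synthetic sequences 0, a 2-layer LSTM classifier is
#' trained on a stratified 80/20 split, and the score is
#' `|held-out accuracy - 0.5|`. A score near 0 means the classifier
#' cannot tell the sets apart (the synthetic set is distributionally
#' faithful); 0.5 means perfect separability. Lower is better.
#'
#' Signals are normalized per channel with statistics pooled over both
#' sets before training.
#'
#' @param real,synth [signal_set()] objects (>= 32 signals each) with
#'   matching channel count and length.
#' @param hidden LSTM hidden size per layer.
#' @param layers Number of stacked LSTM layers.
#' @param epochs Training epoch cap.
#' @param patience Early-stopping patience on held-out loss.
#' @param lr Adam learning rate.
#' @param seed Seed for the split and training.
#' @return A `discriminative_report`: list with `score` in `[0, 0.5]`,
#'   `test_accuracy`, `n_train`, `n_test`.
#' @export
discriminative_score <- function(real, synth, hidden = 64, layers = 2,
                                 epochs = 50, patience = 5, lr = 2e-3,
                                 seed = 1) {
  stopifnot(inherits(real, "signal_set"), inherits(synth, "signal_set"))
  if (n_signals(real) < 32 || n_signals(synth) < 32) {
    stopf("both sets need at least 32 signals")
  }
  if (!identical(dim(real$values)[-1], dim(synth$values)[-1])) {
    stopf("sets must share channel count and length")
  }
  all_ss <- bind_signals(signal_set(real$values), signal_set(synth$values))
  y <- c(rep(1, n_signals(real)), rep(0, n_signals(synth)))
  norm <- fit_norm(all_ss$values)
  x <- apply_norm(ss_to_clb(all_ss$values), norm)

  split <- with_seed(derive_seed(seed, 13L), {
    idx1 <- which(y == 1); idx0 <- which(y == 0)
    te <- c(sample(idx1, max(1L, round(0.2 * length(idx1)))),
            sample(idx0, max(1L, round(0.2 * length(idx0)))))
    tr <- setdiff(seq_along(y), te)
    # carve a small stratified validation slice out of train for early stop
    tr1 <- intersect(tr, idx1); tr0 <- intersect(tr, idx0)
    va <- c(sample(tr1, max(1L, round(0.15 * length(tr1)))),
            sample(tr0, max(1L, round(0.15 * length(tr0)))))
    list(tr = setdiff(tr, va), va = va, te = te)
  })
  fit <- lstm_train(x[, , split$tr, drop = FALSE], y[split$tr],
                    x[, , split$va, drop = FALSE], y[split$va],
                    hidden = hidden, layers = layers, epochs = epochs,
                    patience = patience, lr = lr, seed = seed)
  pr <- lstm_forward(fit$params, x[, , split$te, drop = FALSE])$prob
  acc <- mean((pr > 0.5) == (y[split$te] == 1))
  structure(list(score = abs(acc - 0.5), test_accuracy = acc,
                 n_train = length(split$tr) + length(split$va),
                 n_test = length(split$te)),
            class = "discriminative_report")
}

#' @export
print.discriminative_report <- function(x, ...) {
  cat(sprintf(
    "<discriminative_report> score %.3f (test accuracy %.3f, n=%d/%d)\n",
    x$score, x$test_accuracy, x$n_train, x$n_test))
  invisible(x)
}
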