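# Evaluation suite: classification report against a brute-force oracle,
# wavelet coherence properties, and the discriminative score basics.

test_that("classification_report matches a brute-force confusion oracle", {
  # oracle: direct confusion-matrix counting, written independently
  oracle <- function(yt, yp, K) {
    cm <- matrix(0L, K, K)
    for (i in seq_along(yt)) cm[yt[i] + 1, yp[i] + 1] <- cm[yt[i] + 1, yp[i] + 1] + 1L
    tp <- diag(cm); fp <- colSums(cm) - tp; fn <- rowSums(cm) - tp
    sd0 <- function(a, b) ifelse(b > 0, a / b, 0)
    list(p = sd0(tp, tp + fp), r = sd0(tp, tp + fn),
         f1 = sd0(2 * tp, 2 * tp + fp + fn))
  }
  set.seed(77)
  for (rep in 1:25) {
    K <- sample(2:6, 1)
    n <- sample(c(5, 40, 200), 1)
    yt <- sample(0:(K - 1), n, TRUE)
    yp <- sample(0:(K - 1), n, TRUE)
    got <- classification_report(yt, yp, K)
    want <- oracle(yt, yp, K)
    expect_equal(got$per_class$precision, unname(want$p))
    expect_equal(got$per_class$recall, unname(want$r))
    expect_equal(got$per_class$f1, unname(want$f1))
    expect_equal(got$macro_f1, mean(want$f1))
  }
})

test_that("classification_report handles edge conventions", {
  r <- classification_report(c(0, 0, 1, 1), c(0, 0, 1, 1), 3)
  expect_equal(r$per_class$f1[1:2], c(1, 1))
  expect_equal(r$per_class$f1[3], 0)        # never predicted, never true
  # tp = fp = fn balance: p = r = f1 = 0.5
  yt <- c(rep(0, 5), rep(0, 5), rep(1, 5))
  yp <- c(rep(0, 5), rep(1, 5), rep(0, 5))
  r2 <- classification_report(yt, yp, 2)
  expect_equal(r2$per_class$precision[1], 0.5)
  expect_equal(r2$per_class$recall[1], 0.5)
  expect_equal(r2$per_class$f1[1], 0.5)
  expect_error(classification_report(c(0, 5), c(0, 1), 2), "outside")
})

test_that("self-coherence of a non-constant signal is 1 everywhere", {
  set.seed(5)
  x <- cbf_template(1, 512) + rnorm(512, 0, 0.5)
  cm <- wavelet_coherence_pair(x, x)
  expect_true(all(cm$values >= 0 & cm$values <= 1))
  expect_gt(mean(cm$values), 0.99)
})

test_that("independent white noise has coherence well below 1", {
  set.seed(6)
  vals <- replicate(20, {
    mean(wavelet_coherence_pair(rnorm(512), rnorm(512))$values)
  })
  expect_lt(mean(vals), 0.6)
})

test_that("a small delay preserves coherence at long scales", {
  set.seed(8)
  x <- cbf_template(1, 256) + rnorm(256, 0.2)
  y <- c(x[-(1:4)], x[1:4])                  # lag of 4 samples
  cm <- wavelet_coherence_pair(x, y)
  long <- cm$scales >= 32
  expect_gt(mean(cm$values[long, ]), 0.8)
})

test_that("constant signals yield coherence 0 with a warning", {
  expect_warning(cm <- wavelet_coherence_pair(rep(1, 64), rnorm(64)),
                 "constant")
  expect_true(all(cm$values == 0))
})

test_that("set score is 100 for identity self-pairing and order-symmetric", {
  ss <- generate_simulated(sim_config(n_per_class = 12, length = 64,
                                      n_classes = 1, pattern_var = 4,
                                      seed = 31))
  self <- set_coherence_score(ss, ss, pairing = "identity")
  expect_equal(self$score, 100)
  other <- generate_simulated(sim_config(n_per_class = 12, length = 64,
                                         n_classes = 1, pattern_var = 4,
                                         seed = 32))
  ab <- set_coherence_score(ss, other, n_pairs = 50, seed = 3)
  ba <- set_coherence_score(other, ss, n_pairs = 50, seed = 3)
  # random pairing draws (i, j) identically, so the aggregate statistic
  # is symmetric up to the pairing permutation; scores agree closely
  expect_equal(ab$score, ba$score, tolerance = 2)
  expect_true(all(ab$per_pair >= 0 & ab$per_pair <= 1))
})

test_that("real CBF scores higher against itself than against white noise", {
  ss <- generate_simulated(sim_config(n_per_class = 64, length = 64,
                                      n_classes = 1, pattern_var = 4,
                                      seed = 33))
  other <- generate_simulated(sim_config(n_per_class = 64, length = 64,
                                         n_classes = 1, pattern_var = 4,
                                         seed = 34))
  wn <- white_noise_set(64, 64, seed = 35)
  within <- set_coherence_score(ss, other, n_pairs = 100, seed = 4)$score
  vs_noise <- set_coherence_score(ss, wn, n_pairs = 100, seed = 4)$score
  expect_gt(within, vs_noise + 5)
})

test_that("discriminative score separates disjoint constant sets at 0.5", {
  a <- signal_set(array(0, c(40, 1, 32)))
  b <- signal_set(array(1, c(40, 1, 32)))
  # constant channels: normalize over the pooled sets keeps them distinct
  r <- discriminative_score(a, b, epochs = 30, seed = 1)
  expect_equal(r$test_accuracy, 1)
  expect_equal(r$score, 0.5)
})

test_that("discriminative score validates inputs and bounds", {
  a <- signal_set(array(rnorm(40 * 32), c(40, 1, 32)))
  expect_error(discriminative_score(a, signal_set(array(0, c(10, 1, 32)))),
               "at least 32")
  r <- discriminative_score(a, white_noise_set(40, 32, seed = 2),
                            epochs = 5, seed = 1)
  expect_gte(r$score, 0)
  expect_lte(r$score, 0.5)
  expect_equal(r$score, abs(r$test_accuracy - 0.5))
})
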