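test_that("generator produces the configured shape, labels, and defaults", {
  ss <- generate_simulated(sim_config(n_per_class = 3, seed = 2))
  expect_equal(dim(ss$values), c(15, 1, 512))   # default: 512 steps, 1 channel
  expect_equal(sort(unique(ss$labels)), 0:4)
  expect_equal(as.vector(table(ss$labels)), rep(3L, 5))

  expect_error(sim_config(n_classes = 6), "n_classes")
  expect_error(sim_config(length = 8), "length")
  expect_error(sim_config(noise_sd = -1), ">= 0")
})

test_that("generation is bit-identical under a fixed seed", {
  cf <- sim_config(n_per_class = 5, length = 64, n_classes = 4,
                   pattern_var = 4, seed = 99)
  a <- generate_simulated(cf)
  b <- generate_simulated(cf)
  expect_identical(a$values, b$values)
  expect_identical(a$labels, b$labels)
})

test_that("noiseless cylinder is piecewise constant with two levels", {
  ss <- generate_simulated(sim_config(n_per_class = 1, length = 64,
                                      n_classes = 1, amp_var = 0,
                                      pattern_var = 0, noise_sd = 0))
  vals <- unique(round(ss$values[1, 1, ], 10))
  expect_length(vals, 2)
  expect_true(0 %in% vals)
})

test_that("noiseless templates of distinct classes differ pairwise", {
  tm <- sapply(0:4, cbf_template, length = 128)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_false(isTRUE(all.equal(tm[, i], tm[, j])),
                 info = sprintf("classes %d vs %d", i - 1, j - 1))
  }
})

test_that("additive degradations preserve shape and obey magnitude zero", {
  ss <- generate_simulated(sim_config(n_per_class = 4, length = 64,
                                      n_classes = 2, seed = 3))
  for (kind in c("thermal", "baseline_wander", "motion_artifact")) {
    out <- degrade(ss, degradation_spec(kind, magnitude = 0, seed = 5))
    expect_identical(out$signals$values, ss$values, label = kind)
    out2 <- degrade(ss, degradation_spec(kind, magnitude = 0.5, seed = 5))
    expect_identical(dim(out2$signals$values), dim(ss$values))
    expect_false(identical(out2$signals$values, ss$values))
  }
})

test_that("thermal degradation adds noise of the requested scale", {
  zero <- signal_set(array(0, c(20, 1, 512)))
  out <- degrade(zero, degradation_spec("thermal", magnitude = 0.1, seed = 8))
  expect_lt(abs(sd(out$signals$values) - 0.1) / 0.1, 0.1)
})

test_that("mask_gaps zeroes the right fraction and returns a faithful mask", {
  ss <- generate_simulated(sim_config(n_per_class = 6, length = 512,
                                      n_classes = 1, seed = 4))
  out <- degrade(ss, degradation_spec("mask_gaps", gap_fraction = 0.25,
                                      seed = 9))
  expect_identical(dim(out$mask), dim(ss$values))
  # 384 observed samples per channel (+- 1 for rounding)
  ones <- apply(out$mask, 1, sum)
  expect_true(all(abs(ones - 384) <= 1))
  # observed entries equal the original exactly; gaps are zero
  obs <- out$mask == 1
  expect_identical(out$signals$values[obs], ss$values[obs])
  expect_true(all(out$signals$values[!obs] == 0))
})

test_that("downsample keeps shape, interpolates, and rejects bad factors", {
  ss <- generate_simulated(sim_config(n_per_class = 3, length = 64,
                                      n_classes = 1, seed = 5))
  out <- degrade(ss, degradation_spec("downsample", factor = 4, seed = 1))
  expect_identical(dim(out$signals$values), dim(ss$values))
  # kept samples are exact
  keep <- seq(1, 64, by = 4)
  expect_equal(out$signals$values[1, 1, keep], ss$values[1, 1, keep])
  expect_error(degrade(ss, degradation_spec("downsample", factor = 64)),
               "factor")
})

test_that("degradation is deterministic under a fixed seed", {
  ss <- generate_simulated(sim_config(n_per_class = 3, length = 64,
                                      n_classes = 1, seed = 6))
  for (kind in c("thermal", "baseline_wander", "motion_artifact",
                 "mask_gaps")) {
    a <- degrade(ss, degradation_spec(kind, magnitude = 0.3, seed = 21))
    b <- degrade(ss, degradation_spec(kind, magnitude = 0.3, seed = 21))
    expect_identical(a$signals$values, b$signals$values, label = kind)
  }
})

test_that("make_imbalanced subsamples classes exactly and reproducibly", {
  ss <- generate_simulated(sim_config(n_per_class = 100, length = 64,
                                      n_classes = 2, seed = 7))
  out <- make_imbalanced(ss, c(1.0, 0.1), seed = 3)
  expect_equal(as.vector(table(out$labels)), c(100L, 10L))
  out2 <- make_imbalanced(ss, c(1.0, 0.1), seed = 3)
  expect_identical(out$values, out2$values)
  idf <- make_imbalanced(ss, c(1.0, 1.0), seed = 3)
  expect_identical(idf$values, ss$values)
  expect_error(make_imbalanced(ss, c(1.0, 0)), "fractions")
})
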