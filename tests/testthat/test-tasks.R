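# Task plumbing with a micro model (quality checks live in the
# acceptance suite; here only contracts are exercised).

micro_label_fit <- function() {
  memo("micro_label_fit", function() {
    ss <- generate_simulated(sim_config(n_per_class = 24, length = 16,
                                        n_classes = 2, pattern_var = 1,
                                        seed = 21))
    train_diffusion(ss,
                    train_config(T_steps = 20, schedule_kind = "cosine",
                                 max_epochs = 3, patience = 3,
                                 batch_size = 16, seed = 2),
                    mode = "label",
                    unet = unet_config(16, in_channels = 1,
                                       base_channels = 8,
                                       channel_mults = c(1, 2),
                                       attention = c(FALSE, TRUE),
                                       time_embed_dim = 8, n_classes = 2))
  })
}

micro_signal_fit <- function() {
  memo("micro_signal_fit", function() {
    ss <- generate_simulated(sim_config(n_per_class = 32, length = 16,
                                        n_classes = 1, pattern_var = 1,
                                        seed = 22))
    train_diffusion(ss,
                    train_config(T_steps = 20, schedule_kind = "cosine",
                                 max_epochs = 3, patience = 3,
                                 batch_size = 16, seed = 2),
                    mode = "signal",
                    degradation = degradation_spec("mask_gaps",
                                                   gap_fraction = 0.25,
                                                   seed = 3),
                    unet = unet_config(16, in_channels = 1,
                                       base_channels = 8,
                                       channel_mults = c(1, 2),
                                       attention = c(FALSE, TRUE),
                                       time_embed_dim = 8,
                                       cond_channels = 1))
  })
}

test_that("training runs, records history, and is seed-deterministic", {
  fit <- micro_label_fit()
  expect_s3_class(fit, "diffusion_model")
  expect_true(nrow(fit$history) >= 1)
  expect_true(all(is.finite(fit$history$val_total)))
  ss <- generate_simulated(sim_config(n_per_class = 24, length = 16,
                                      n_classes = 2, pattern_var = 1,
                                      seed = 21))
  fit2 <- train_diffusion(ss,
                          train_config(T_steps = 20,
                                       schedule_kind = "cosine",
                                       max_epochs = 3, patience = 3,
                                       batch_size = 16, seed = 2),
                          mode = "label", unet = fit$unet)
  expect_identical(fit$history, fit2$history)
})

test_that("early stopping halts after patience exhausts", {
  ss <- generate_simulated(sim_config(n_per_class = 16, length = 16,
                                      n_classes = 1, seed = 23))
  # a huge learning rate makes validation worsen immediately
  fit <- train_diffusion(ss,
                         train_config(T_steps = 20, max_epochs = 20,
                                      patience = 1, lr = 1.0,
                                      batch_size = 16, seed = 3),
                         mode = "uncond",
                         unet = unet_config(16, in_channels = 1,
                                            base_channels = 8,
                                            channel_mults = c(1, 2),
                                            attention = c(FALSE, FALSE),
                                            time_embed_dim = 8))
  expect_lt(nrow(fit$history), 20)
})

test_that("sampling honours shape, determinism, and mode guards", {
  fit <- micro_label_fit()
  g <- sample_diffusion(fit, 5, label = 1, seed = 4)
  expect_equal(dim(g$values), c(5, 1, 16))
  expect_true(all(is.finite(g$values)))
  expect_true(all(g$labels == 1))
  g2 <- sample_diffusion(fit, 5, label = 1, seed = 4)
  expect_identical(g$values, g2$values)
  expect_error(sample_diffusion(fit, 2), "label")
  expect_error(sample_diffusion(fit, 2, label = 9), "label set")
  expect_error(sample_diffusion(fit, 2, label = 1,
                                cond = signal_set(array(0, c(2, 1, 16)))),
               "cond")
})

test_that("an untrained network still samples finite values", {
  sch <- make_schedule(20, "cosine")
  fit <- structure(list(
    model = build_unet(unet_config(16, in_channels = 1, base_channels = 8,
                                   channel_mults = c(1, 2),
                                   attention = c(FALSE, FALSE),
                                   time_embed_dim = 8), seed = 1),
    schedule = sch, mode = "uncond",
    norm = list(center = 0, scale = 1),
    n_channels = 1L, length = 16L, label_set = NULL),
    class = "diffusion_model")
  g <- sample_diffusion(fit, 3, seed = 5)
  expect_true(all(is.finite(g$values)))
})

test_that("impute copies observed samples back bit-exactly", {
  fit <- micro_signal_fit()
  ss <- generate_simulated(sim_config(n_per_class = 6, length = 16,
                                      n_classes = 1, pattern_var = 1,
                                      seed = 24))
  dg <- degrade(ss, degradation_spec("mask_gaps", gap_fraction = 0.25,
                                     seed = 5))
  res <- impute(dg$signals, dg$mask, fit, reference = ss, seed = 6)
  obs <- dg$mask == 1
  expect_identical(res$restored$values[obs], dg$signals$values[obs])
  expect_true(res$mse_before >= 0 && res$mse_after >= 0)
  # gap_fraction = 0: nothing to impute, output equals input exactly
  dg0 <- degrade(ss, degradation_spec("mask_gaps", gap_fraction = 0,
                                      seed = 5))
  res0 <- impute(dg0$signals, dg0$mask, fit, seed = 6)
  expect_identical(res0$restored$values, ss$values)
  expect_error(impute(dg$signals, dg$mask[1:2, , , drop = FALSE], fit),
               "mask")
})

test_that("upsample restores full-length signals from decimated input", {
  fit <- micro_signal_fit()
  ss <- generate_simulated(sim_config(n_per_class = 4, length = 16,
                                      n_classes = 1, pattern_var = 1,
                                      seed = 27))
  low <- degrade(ss, degradation_spec("downsample", factor = 4, seed = 6))
  res <- upsample(low$signals, fit, reference = ss, seed = 7, n_draws = 1)
  expect_identical(dim(res$restored$values), dim(ss$values))
  expect_true(all(is.finite(res$restored$values)))
  expect_true(res$mse_before >= 0 && res$mse_after >= 0)
})

test_that("restoration guards reject wrong modes and lengths", {
  lfit <- micro_label_fit()
  sfit <- micro_signal_fit()
  ss <- generate_simulated(sim_config(n_per_class = 4, length = 16,
                                      n_classes = 1, seed = 25))
  expect_error(denoise(ss, lfit), "signal-conditional")
  long <- generate_simulated(sim_config(n_per_class = 4, length = 32,
                                        n_classes = 1, seed = 25))
  expect_error(denoise(long, sfit), "length")
})

test_that("balance_with_synthesis hits target counts with labelled synthesis", {
  fit <- micro_label_fit()
  ss <- generate_simulated(sim_config(n_per_class = 24, length = 16,
                                      n_classes = 2, pattern_var = 1,
                                      seed = 21))
  imb <- make_imbalanced(ss, c(1.0, 0.25), seed = 9)   # counts 24, 6
  plan <- augmentation_plan(c("0" = 24, "1" = 24))
  bal <- balance_with_synthesis(imb, fit, plan, seed = 10)
  expect_equal(as.vector(table(bal$labels)), c(24L, 24L))
  expect_equal(attr(bal, "generated_counts")[["1"]], 18L)
  # plan equal to current counts: nothing generated
  same <- balance_with_synthesis(imb, fit,
                                 augmentation_plan(c("0" = 24, "1" = 6)),
                                 seed = 10)
  expect_equal(as.vector(table(same$labels)), c(24L, 6L))
  expect_equal(sum(attr(same, "generated_counts")), 0L)
  expect_error(balance_with_synthesis(imb, fit,
                                      augmentation_plan(c("7" = 5)),
                                      seed = 1),
               "label set")
})

test_that("imbalance_experiment refuses leaked test sets and reports F1", {
  fit <- micro_label_fit()
  ss <- generate_simulated(sim_config(n_per_class = 24, length = 16,
                                      n_classes = 2, pattern_var = 1,
                                      seed = 21))
  te <- generate_simulated(sim_config(n_per_class = 8, length = 16,
                                      n_classes = 2, pattern_var = 1,
                                      seed = 26))
  expect_error(imbalance_experiment(ss, subset_signals(ss, 1:4), fit,
                                    augmentation_plan(c("0" = 24, "1" = 24)),
                                    classifier_config(epochs = 2), seed = 1),
               "leakage")
  res <- imbalance_experiment(ss, te, fit,
                              augmentation_plan(c("0" = 24, "1" = 24)),
                              classifier_config(epochs = 3), seed = 1)
  expect_s3_class(res$before, "class_metrics")
  expect_s3_class(res$after, "class_metrics")
  expect_true(all(res$before$per_class$f1 >= 0 & res$before$per_class$f1 <= 1))
  expect_true(all(res$after$per_class$f1 >= 0 & res$after$per_class$f1 <= 1))
})

test_that("identical data give identical classifier F1 under one seed", {
  d <- cbf_three_class()
  tr <- subset_signals(d$train, 1:90)
  te <- subset_signals(d$test, 1:45)
  a <- train_cnn_classifier(tr, classifier_config(epochs = 5), seed = 3)
  b <- train_cnn_classifier(tr, classifier_config(epochs = 5), seed = 3)
  expect_identical(predict(a, te), predict(b, te))
})
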