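#' @name restoration
#' @title Signal-conditional restoration tasks
#'
#' @description
#' A signal-conditional diffusion model trained on (clean, degraded)
#' pairs restores a degraded input by conditioning every reverse step on
#' it: [denoise()] removes additive noise, [impute()] fills masked gaps
#' (observed samples are copied back verbatim, so only gaps are
#' synthesized), and [upsample()] reconstructs detail lost to
#' decimation (the low-resolution input must already be interpolated to
#' the model's native length, as [degrade()]'s `downsample` does).
#' Each returns a `task_result` with the restored signals and, when a
#' clean reference is supplied, the mean squared error of the input
#' (`mse_before`) and of the restoration (`mse_after`).
NULL

task_result <- function(restored, reference, mse_before, mse_after) {
  structure(list(restored = restored, reference = reference,
                 mse_before = mse_before, mse_after = mse_after),
            class = "task_result")
}

#' @export
print.task_result <- function(x, ...) {
  cat("<task_result>")
  if (!is.na(x$mse_before)) {
    cat(sprintf(" mse before %.5g after %.5g", x$mse_before, x$mse_after))
  }
  cat("\n")
  invisible(x)
}

mse_of <- function(a, b) if (is.null(b)) NA_real_ else mean((a - b)^2)

check_signal_model <- function(model) {
  if (!inherits(model, "diffusion_model") || model$mode != "signal") {
    stopf("a signal-conditional diffusion_model is required")
  }
}

## posterior-mean restoration estimate: average of n_draws conditional
## ancestral samples (each draw is a sample from p(x0 | condition);
## averaging reduces the draw variance of the point estimate)
conditional_mean <- function(model, cond_set, n_draws, seed) {
  n <- n_signals(cond_set)
  acc <- NULL
  for (k in seq_len(n_draws)) {
    g <- sample_diffusion(model, n, cond = cond_set,
                          seed = derive_seed(seed, 7000L + k),
                          var_mode = "beta_tilde")
    acc <- if (is.null(acc)) g$values else acc + g$values
  }
  signal_set(acc / n_draws, labels = cond_set$labels,
             channel_names = cond_set$channel_names)
}

#' @rdname restoration
#' @param noisy,gappy,lowres Degraded [signal_set()] input.
#' @param model A signal-mode `diffusion_model`.
#' @param reference Optional clean [signal_set()] for MSE reporting.
#' @param seed Sampling seed.
#' @param n_draws Conditional draws averaged into the restoration point
#'   estimate (default 4; 1 returns a single posterior sample).
#' @export
denoise <- function(noisy, model, reference = NULL, seed = 1, n_draws = 4) {
  check_signal_model(model)
  stopifnot(inherits(noisy, "signal_set"))
  if (dim(noisy$values)[3] != model$length) {
    stopf("condition length %d does not match the model length %d",
          dim(noisy$values)[3], model$length)
  }
  restored <- conditional_mean(model, noisy, n_draws, seed)
  ref <- if (!is.null(reference)) reference$values
  task_result(restored, reference,
              mse_of(noisy$values, ref), mse_of(restored$values, ref))
}

#' @rdname restoration
#' @param mask Binary observation mask shaped like `gappy$values`
#'   (1 = observed), as returned by [degrade()].
#' @export
impute <- function(gappy, mask, model, reference = NULL, seed = 1,
                   n_draws = 4) {
  check_signal_model(model)
  stopifnot(inherits(gappy, "signal_set"))
  if (!identical(dim(mask), dim(gappy$values))) {
    stopf("mask shape does not match the signals")
  }
  restored <- conditional_mean(model, gappy, n_draws, seed)
  vals <- restored$values
  obs <- mask == 1
  vals[obs] <- gappy$values[obs]            # copy-back contract
  restored <- signal_set(vals, labels = gappy$labels,
                         channel_names = gappy$channel_names)
  ref <- if (!is.null(reference)) reference$values
  task_result(restored, reference,
              mse_of(gappy$values, ref), mse_of(restored$values, ref))
}

#' @rdname restoration
#' @export
upsample <- function(lowres, model, reference = NULL, seed = 1,
                     n_draws = 4) {
  check_signal_model(model)
  stopifnot(inherits(lowres, "signal_set"))
  if (dim(lowres$values)[3] != model$length) {
    stopf("low-resolution input must be interpolated to the model length %d",
          model$length)
  }
  restored <- conditional_mean(model, lowres, n_draws, seed)
  ref <- if (!is.null(reference)) reference$values
  task_result(restored, reference,
              mse_of(lowres$values, ref), mse_of(restored$values, ref))
}

#' Augmentation plan
#'
#' Target per-class sample counts after augmentation, named by class
#' label (e.g. `c("0" = 100, "1" = 100)`).
#'
#' @param per_class_target Named integer vector of target counts.
#' @return An `augmentation_plan`.
#' @export
augmentation_plan <- function(per_class_target) {
  if (is.null(names(per_class_target))) {
    stopf("per_class_target must be named by class label")
  }
  if (any(per_class_target < 0)) stopf("targets must be >= 0")
  structure(list(per_class_target = per_class_target),
            class = "augmentation_plan")
}

#' Balance a training set with label-conditional synthesis
#'
#' For every class below its target count, draws the deficit from a
#' label-conditional diffusion model with that label, then concatenates
#' real and synthetic signals and shuffles (seeded). Post-condition:
#' per-class counts equal the plan exactly (classes already at or above
#' target are left untouched).
#'
#' @param train Labelled [signal_set()].
#' @param model A label-mode `diffusion_model` trained on `train`.
#' @param plan An [augmentation_plan()].
#' @param seed Seed for sampling and the final shuffle.
#' @return A [signal_set()] with balanced class counts.
#' @export
balance_with_synthesis <- function(train, model, plan, seed = 1) {
  stopifnot(inherits(train, "signal_set"), inherits(plan, "augmentation_plan"))
  if (!inherits(model, "diffusion_model") || model$mode != "label") {
    stopf("a label-conditional diffusion_model is required")
  }
  if (is.null(train$labels)) stopf("labelled training data required")
  counts <- table(train$labels)
  pieces <- list(train)
  gen_counts <- integer(0)
  for (cls_name in names(plan$per_class_target)) {
    cls <- as.integer(cls_name)
    if (!cls %in% model$label_set) {
      stopf("class %s is not in the model's label set", cls_name)
    }
    have <- if (cls_name %in% names(counts)) counts[[cls_name]] else 0L
    need <- plan$per_class_target[[cls_name]] - have
    gen_counts[cls_name] <- max(0L, need)
    if (need > 0L) {
      synth <- sample_diffusion(model, need, label = cls,
                                seed = derive_seed(seed, 100L + cls))
      pieces[[length(pieces) + 1L]] <- synth
    }
  }
  out <- do.call(bind_signals, pieces)
  perm <- with_seed(derive_seed(seed, 999L), sample.int(n_signals(out)))
  out <- subset_signals(out, perm)
  attr(out, "generated_counts") <- gen_counts
  out
}

#' Class-imbalance augmentation experiment
#'
#' Quantifies the downstream value of synthetic signals: the pinned
#' 1D-CNN classifier is trained once on the imbalanced training set and
#' once on the same set balanced by [balance_with_synthesis()], and both
#' are evaluated on an untouched test set (never seen by the generator;
#' disjointness is asserted). Returns the per-class F1 report for both.
#'
#' @param train Labelled, imbalanced [signal_set()].
#' @param test Labelled [signal_set()]; must be disjoint from `train`.
#' @param model Label-conditional `diffusion_model` trained on `train`.
#' @param plan An [augmentation_plan()].
#' @param classifier_config A [classifier_config()].
#' @param seed Seed controlling augmentation and both classifier fits.
#' @return List with `before` and `after` ([classification_report()]
#'   objects), `balanced_counts`, and `macro_f1_before` / `macro_f1_after`.
#' @export
imbalance_experiment <- function(train, test, model, plan,
                                 classifier_config = classifier_config(),
                                 seed = 1) {
  stopifnot(inherits(train, "signal_set"), inherits(test, "signal_set"))
  if (is.null(train$labels) || is.null(test$labels)) {
    stopf("both sets must be labelled")
  }
  # leakage check: no test signal may appear in the training set
  key <- function(v) apply(matrix(v, dim(v)[1]), 1, function(r) {
    paste(signif(r, 12), collapse = ",")
  })
  if (any(key(test$values) %in% key(train$values))) {
    stopf("train/test leakage: shared signals detected")
  }
  n_classes <- length(unique(c(train$labels, test$labels)))
  before_clf <- train_cnn_classifier(train, classifier_config, seed = seed)
  pred_b <- predict(before_clf, test)
  before <- classification_report(test$labels, pred_b, n_classes)

  balanced <- balance_with_synthesis(train, model, plan, seed = seed)
  after_clf <- train_cnn_classifier(balanced, classifier_config, seed = seed)
  pred_a <- predict(after_clf, test)
  after <- classification_report(test$labels, pred_a, n_classes)

  list(before = before, after = after,
       balanced_counts = table(balanced$labels),
       macro_f1_before = before$macro_f1,
       macro_f1_after = after$macro_f1)
}
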