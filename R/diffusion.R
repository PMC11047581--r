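#' Training configuration for the diffusion model
#'
#' @param T_steps Diffusion steps (>= 10 for training).
#' @param schedule_kind `"linear"` or `"cosine"` (see [make_schedule()]).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience, in epochs without improvement
#'   of the validation ELBO (>= 1).
#' @param ema_decay Optional exponential-moving-average decay for the
#'   weights (e.g. 0.999), or `NULL` to disable (the default, which keeps
#'   small runs exactly reproducible step for step).
#' @param lambda_vlb Weight of the variational-bound term in the hybrid
#'   loss `L_simple + lambda * L_vlb`.
#' @param seed Seed controlling the split, batching, and noise draws.
#' @return A `train_config` list.
#' @export
train_config <- function(T_steps = 100, schedule_kind = "cosine", lr = 2e-3,
                         batch_size = 16, max_epochs = 30, patience = 10,
                         ema_decay = NULL, lambda_vlb = 1e-3, seed = 1) {
  if (patience < 1) stopf("patience must be >= 1")
  if (T_steps < 10) stopf("T_steps must be >= 10")
  structure(list(T_steps = as.integer(T_steps),
                 schedule_kind = schedule_kind, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 ema_decay = ema_decay, lambda_vlb = lambda_vlb,
                 seed = as.integer(seed)),
            class = "train_config")
}

## per-channel affine map to [-1, 1] fitted on the training set
fit_norm <- function(values) {
  C <- dim(values)[2]
  center <- numeric(C); scale <- numeric(C)
  for (ch in seq_len(C)) {
    rng <- range(values[, ch, ])
    center[ch] <- mean(rng)
    scale[ch] <- max((rng[2] - rng[1]) / 2, 1e-8)
  }
  list(center = center, scale = scale)
}

apply_norm <- function(x_clb, norm) {
  (x_clb - norm$center) / norm$scale        # recycles along channel axis
}

invert_norm <- function(x_clb, norm) {
  x_clb * norm$scale + norm$center
}

## hybrid loss on one batch; x0, eps, cond are (C, L, B) arrays in
## normalized units; returns the breakdown and, optionally, parameter grads
diffusion_loss <- function(model, x0, tvec, eps, schedule, lambda_vlb,
                           label = NULL, cond = NULL, want_grads = TRUE) {
  xt <- q_sample(x0, tvec, eps, schedule)
  fw <- unet_forward(model, xt, tvec, label = label, cond = cond)
  N <- length(x0)
  resid <- fw$eps - eps
  simple <- sum(resid * resid) / N

  rm_ <- reverse_moments(xt, tvec, fw$eps, fw$v, schedule)
  po <- posterior_moments(x0, xt, tvec, schedule)
  d <- dim(x0)
  per <- prod(d[-3])
  t_el <- rep(tvec, each = per)               # per-element timestep
  delta2 <- (po$mu - rm_$mu)^2                # mu_theta detached below
  inv_var <- exp(-rm_$log_var)
  kl <- 0.5 * (rm_$log_var - log(pmax(po$var, 1e-12)) +
                 (po$var + delta2) * inv_var - 1)
  nll <- 0.5 * (log(2 * pi) + rm_$log_var + (x0 - rm_$mu)^2 * inv_var)
  vlb_el <- ifelse(t_el == 1L, nll, kl)
  vlb <- sum(vlb_el) / N
  total <- simple + lambda_vlb * vlb
  out <- list(total = total, simple = simple, vlb = vlb)
  if (!want_grads) return(out)

  # gradients: simple trains eps_theta; the vlb term trains only v_theta
  d_eps <- 2 * resid / N
  c_el <- ifelse(t_el == 1L, (x0 - rm_$mu)^2, po$var + delta2)
  dlogvar <- (0.5 - 0.5 * c_el * inv_var) * (lambda_vlb / N)
  lb <- log(schedule$beta[tvec])
  lt <- schedule$log_beta_tilde_clipped[tvec]
  spread <- array(rep(lb - lt, each = per), d)
  d_v <- dlogvar * spread
  out$grads <- unet_backward(model, fw$cache, d_eps, d_v)
  out
}

#' Evidence-lower-bound loss breakdown
#'
#' Computes the hybrid training objective on a batch: the denoising
#' mean-squared error `simple` over uniformly sampled timesteps, the
#' variational-bound term `vlb` (per-step KL between the Gaussian forward
#' posterior and the reverse model for t > 1, Gaussian log-likelihood at
#' t = 1), and `total = simple + lambda_vlb * vlb`. The reverse mean is
#' treated as fixed in the vlb term, so that term informs only the learned
#' variance.
#'
#' @param x0 Normalized signals, array `(C, L, B)` or a [signal_set()]
#'   (converted and used as-is, without rescaling).
#' @param model A `unet_model`.
#' @param schedule A [make_schedule()] object.
#' @param lambda_vlb Weight of the vlb term.
#' @param seed Seed for the timestep and noise draws.
#' @param label,cond Optional conditioning (0-based label vector / `(C, L,
#'   B)` array).
#' @return List with `total`, `simple`, `vlb`.
#' @export
elbo_loss <- function(x0, model, schedule, lambda_vlb = 1e-3, seed = 1,
                      label = NULL, cond = NULL) {
  if (inherits(x0, "signal_set")) x0 <- ss_to_clb(x0$values)
  B <- dim(x0)[3]
  with_seed(seed, {
    tvec <- sample.int(schedule$T_steps, B, replace = TRUE)
    eps <- array(stats::rnorm(length(x0)), dim(x0))
    out <- diffusion_loss(model, x0, tvec, eps, schedule, lambda_vlb,
                          label = label, cond = cond, want_grads = FALSE)
  })
  if (!all(is.finite(unlist(out[c("total", "simple", "vlb")])))) {
    stopf("non-finite ELBO (simple=%g, vlb=%g)", out$simple, out$vlb)
  }
  out
}

#' Train a diffusion model on a signal set
#'
#' Fits the 1D U-Net noise model by minimizing the hybrid ELBO objective
#' with Adam, using a seeded 90/10 train/validation split and early
#' stopping on the validation ELBO. Signals are normalized per channel to
#' `[-1, 1]` before training; the inverse transform is applied to
#' everything the model generates.
#'
#' Modes: `"uncond"` models the plain data distribution; `"label"` injects
#' a class embedding into every residual block (requires labelled data);
#' `"signal"` trains a restoration model on (clean, degraded) pairs, where
#' each clean batch is degraded afresh every epoch by `degradation` so the
#' model learns the degradation family rather than fixed pairs.
#'
#' @param data A [signal_set()].
#' @param config A [train_config()].
#' @param mode `"uncond"`, `"label"`, or `"signal"`.
#' @param unet Optional [unet_config()]; a default sized to the data is
#'   built when omitted.
#' @param degradation A [degradation_spec()] (signal mode only).
#' @param val_fraction Validation fraction of the data (default 0.1).
#' @param verbose Print per-epoch losses.
#' @param init_from Optional earlier `diffusion_model` whose weights
#'   warm-start training (e.g. fine-tuning on one subject's signals).
#' @return A `diffusion_model` checkpoint: best-validation network
#'   weights, schedule, configs, normalization statistics, mode tag, label
#'   set, and the training history.
#' @export
train_diffusion <- function(data, config = train_config(),
                            mode = c("uncond", "label", "signal"),
                            unet = NULL, degradation = NULL,
                            val_fraction = 0.1, verbose = FALSE,
                            init_from = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "signal_set"))
  d <- dim(data$values)
  n <- d[1]; C <- d[2]; L <- d[3]
  if (mode == "label" && is.null(data$labels)) stopf("label mode needs labels")
  if (mode == "signal" && is.null(degradation)) {
    stopf("signal mode needs a degradation_spec")
  }
  label_set <- if (mode == "label") sort(unique(data$labels))
  if (is.null(unet)) {
    unet <- unet_config(L, in_channels = C,
                        n_classes = if (mode == "label") length(label_set),
                        cond_channels = if (mode == "signal") C)
  }
  schedule <- make_schedule(config$T_steps, config$schedule_kind)
  norm <- fit_norm(data$values)

  model <- if (!is.null(init_from)) init_from$model
           else build_unet(unet, seed = derive_seed(config$seed, 11L))
  opt <- adam_init(model$params)
  ema <- if (!is.null(config$ema_decay)) model$params

  hist <- data.frame(epoch = integer(), train_total = numeric(),
                     val_total = numeric(), val_simple = numeric())
  best <- list(val = Inf, params = model$params, epoch = 0L)

  with_seed(derive_seed(config$seed, 23L), {
    val_idx <- sample.int(n, max(1L, round(val_fraction * n)))
    tr_idx <- setdiff(seq_len(n), val_idx)
    lab_of <- function(idx) {
      if (mode != "label") NULL
      else match(data$labels[idx], label_set) - 1L
    }
    xall <- ss_to_clb(data$values)            # (C, L, n), original units
    x_val <- apply_norm(xall[, , val_idx, drop = FALSE], norm)
    # fixed validation noise/timesteps: a low-variance ELBO estimate,
    # comparable across epochs for the early-stopping rule
    t_val <- sample.int(schedule$T_steps, length(val_idx), replace = TRUE)
    eps_val <- array(stats::rnorm(length(x_val)), dim(x_val))
    cond_val <- NULL
    if (mode == "signal") {
      dv <- degradation; dv$seed <- derive_seed(config$seed, 31L)
      degv <- degrade(subset_signals(data, val_idx), dv)
      cond_val <- apply_norm(ss_to_clb(degv$signals$values), norm)
    }

    bad <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      cond_all <- NULL
      if (mode == "signal") {
        de <- degradation; de$seed <- derive_seed(config$seed, 1000L + epoch)
        dge <- degrade(data, de)
        cond_all <- ss_to_clb(dge$signals$values)
      }
      ord <- sample(tr_idx)
      tot <- 0; nb <- 0L
      for (b0 in seq(1L, length(ord), by = config$batch_size)) {
        bi <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
        x0 <- apply_norm(xall[, , bi, drop = FALSE], norm)
        tvec <- sample.int(schedule$T_steps, length(bi), replace = TRUE)
        eps <- array(stats::rnorm(length(x0)), dim(x0))
        cond <- if (mode == "signal") {
          apply_norm(cond_all[, , bi, drop = FALSE], norm)
        }
        ls <- diffusion_loss(model, x0, tvec, eps, schedule,
                             config$lambda_vlb, label = lab_of(bi),
                             cond = cond)
        if (!is.finite(ls$total)) {
          warning("non-finite training loss; stopping at last good checkpoint")
          bad <- Inf
          break
        }
        grads <- clip_grads(ls$grads, 1)
        st <- adam_step(model$params, grads, opt, config$lr)
        model$params <- st$params
        opt <- st$state
        if (!is.null(ema)) {
          ema <- nested_map(function(e, p) {
            config$ema_decay * e + (1 - config$ema_decay) * p
          }, ema, model$params)
        }
        tot <- tot + ls$total; nb <- nb + 1L
      }
      if (is.infinite(bad)) break
      eval_model <- model
      if (!is.null(ema)) eval_model$params <- ema
      vl <- diffusion_loss(eval_model, x_val, t_val, eps_val, schedule,
                           config$lambda_vlb, label = lab_of(val_idx),
                           cond = cond_val, want_grads = FALSE)
      hist[nrow(hist) + 1L, ] <- list(epoch, tot / max(nb, 1L),
                                      vl$total, vl$simple)
      if (verbose) {
        log_msg("INFO", "epoch %d train %.4f val %.4f (simple %.4f)",
                epoch, tot / max(nb, 1L), vl$total, vl$simple)
      }
      if (vl$total < best$val - 1e-6) {
        best <- list(val = vl$total,
                     params = if (is.null(ema)) model$params else ema,
                     epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= config$patience) break
      }
    }
  })

  model$params <- best$params
  structure(list(model = model, schedule = schedule, config = config,
                 unet = unet, mode = mode, norm = norm,
                 label_set = label_set, degradation = degradation,
                 n_channels = C, length = L, history = hist,
                 best_epoch = best$epoch),
            class = "diffusion_model")
}

#' @export
print.diffusion_model <- function(x, ...) {
  cat(sprintf(
    "<diffusion_model> mode=%s T=%d (%s) %d channels x %d timesteps, %d params\n",
    x$mode, x$schedule$T_steps, x$schedule$kind, x$n_channels, x$length,
    n_params(x$model)))
  cat(sprintf("  trained %d epochs (best val ELBO at epoch %d)\n",
              nrow(x$history), x$best_epoch))
  invisible(x)
}

#' Ancestral sampling from a trained diffusion model
#'
#' Draws `x_T` from a standard normal and iterates the learned reverse
#' kernel down to t = 1, adding Gaussian noise scaled by the learned
#' standard deviation at every step except the last. Outputs are mapped
#' back to the original signal units.
#'
#' @param fit A `diffusion_model` from [train_diffusion()].
#' @param n Number of signals to generate.
#' @param label Class label(s) for a label-conditional model (values from
#'   the training label set; scalar or length-`n`).
#' @param cond Conditioning signals for a signal-conditional model: a
#'   [signal_set()] or `(n, C, L)` array in original units.
#' @param seed RNG seed.
#' @param clip_denoised Clamp the implied clean-signal estimate to the
#'   normalized training range `[-1, 1]` at every reverse step before
#'   forming the posterior mean (the standard stabilization for ancestral
#'   sampling; equals the raw reverse mean whenever the estimate is in
#'   range).
#' @param var_mode Reverse-kernel variance: `"learned"` uses the
#'   network's log-interpolation between the two analytic extremes;
#'   `"beta_tilde"` fixes it to the posterior variance lower bound;
#'   `"beta"` to the upper bound.
#' @return A [signal_set()] of `n` generated signals.
#' @export
sample_diffusion <- function(fit, n, label = NULL, cond = NULL, seed = 1,
                             clip_denoised = TRUE,
                             var_mode = c("learned", "beta_tilde", "beta")) {
  var_mode <- match.arg(var_mode)
  stopifnot(inherits(fit, "diffusion_model"), n >= 1)
  if (fit$mode == "label") {
    if (is.null(label)) stopf("label-conditional model: `label` required")
    label <- rep_len(label, n)
    lab_idx <- match(label, fit$label_set) - 1L
    if (anyNA(lab_idx)) stopf("label not in the model's label set")
  } else if (!is.null(label)) {
    stopf("model mode is %s: `label` not accepted", fit$mode)
  } else lab_idx <- NULL
  condn <- NULL
  if (fit$mode == "signal") {
    if (is.null(cond)) stopf("signal-conditional model: `cond` required")
    cv <- if (inherits(cond, "signal_set")) cond$values else cond
    if (is.matrix(cv)) cv <- array(cv, c(nrow(cv), 1L, ncol(cv)))
    if (dim(cv)[1] != n) stopf("`cond` must hold n = %d signals", n)
    if (dim(cv)[2] != fit$n_channels || dim(cv)[3] != fit$length) {
      stopf("`cond` dimensions must match the model (%d x %d)",
            fit$n_channels, fit$length)
    }
    condn <- apply_norm(ss_to_clb(cv), fit$norm)
  } else if (!is.null(cond)) {
    stopf("model mode is %s: `cond` not accepted", fit$mode)
  }
  sch <- fit$schedule
  x <- with_seed(seed, {
    x <- array(stats::rnorm(fit$n_channels * fit$length * n),
               c(fit$n_channels, fit$length, n))
    for (t in rev(seq_len(sch$T_steps))) {
      fw <- unet_forward(fit$model, x, rep(t, n), label = lab_idx,
                         cond = condn)
      vv <- switch(var_mode, learned = fw$v,
                   beta_tilde = 0 * fw$v, beta = 1 + 0 * fw$v)
      mo <- reverse_moments(x, rep(t, n), fw$eps, vv, sch)
      if (clip_denoised) {
        ab <- sch$alpha_bar[t]
        x0hat <- pmin(pmax((x - sqrt(1 - ab) * fw$eps) / sqrt(ab), -1), 1)
        mo$mu <- posterior_moments(x0hat, x, rep(t, n), sch)$mu
      }
      x <- mo$mu
      if (t > 1L) {
        z <- array(stats::rnorm(length(x)), dim(x))
        x <- x + exp(0.5 * mo$log_var) * z
      }
    }
    x
  })
  vals <- clb_to_ss(invert_norm(x, fit$norm))
  signal_set(vals, labels = if (!is.null(label)) as.integer(label))
}
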