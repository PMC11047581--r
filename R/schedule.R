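#' Build a diffusion noise schedule
#'
#' Precomputes the per-step noise variances \eqn{\beta_t} and the derived
#' tables used everywhere in the forward and reverse processes:
#' \eqn{\alpha_t = 1 - \beta_t}, the cumulative signal-retention product
#' \eqn{\bar\alpha_t = \prod_{s \le t} \alpha_s}, and the posterior
#' variance \eqn{\tilde\beta_t = \beta_t (1 - \bar\alpha_{t-1}) /
#' (1 - \bar\alpha_t)} with the convention \eqn{\bar\alpha_0 = 1} (so
#' \eqn{\tilde\beta_1 = 0}).
#'
#' Two schedule shapes are supported. `linear` spaces \eqn{\beta_t} evenly
#' from 1e-4 to 0.02 (the standard DDPM range, sized for T around 1000).
#' `cosine` follows the squared-cosine \eqn{\bar\alpha} curve with offset
#' 0.008 and \eqn{\beta_t} clipped at 0.999; it drives \eqn{\bar\alpha_T}
#' essentially to zero at any T, which makes it the appropriate choice for
#' short schedules.
#'
#' @param T_steps Total diffusion steps (>= 2).
#' @param schedule_kind `"linear"` or `"cosine"`.
#' @return A `diffusion_schedule` list with vectors `beta`, `alpha`,
#'   `alpha_bar`, `beta_tilde` (length `T_steps`, indexed by t = 1..T) and
#'   `log_beta_tilde_clipped` (t = 1 entry replaced by the t = 2 value, for
#'   the learned-variance interpolation where log 0 is unusable).
#' @export
make_schedule <- function(T_steps, schedule_kind = c("linear", "cosine")) {
  schedule_kind <- match.arg(schedule_kind)
  if (T_steps < 2) stopf("T_steps must be >= 2")
  T_steps <- as.integer(T_steps)
  if (schedule_kind == "linear") {
    beta <- seq(1e-4, 0.02, length.out = T_steps)
  } else {
    s <- 0.008
    f <- function(t) cos(((t / T_steps + s) / (1 + s)) * pi / 2)^2
    ab <- f(0:T_steps) / f(0)
    beta <- pmin(1 - ab[-1] / ab[-(T_steps + 1)], 0.999)
    beta <- pmax(beta, 1e-8)
  }
  alpha <- 1 - beta
  alpha_bar <- cumprod(alpha)
  alpha_bar_prev <- c(1, alpha_bar[-T_steps])          # alpha_bar_0 := 1
  beta_tilde <- (1 - alpha_bar_prev) / (1 - alpha_bar) * beta
  lbt <- log(beta_tilde)
  if (T_steps >= 2) lbt[1] <- log(beta_tilde[2])
  structure(list(T_steps = T_steps, kind = schedule_kind, beta = beta,
                 alpha = alpha, alpha_bar = alpha_bar,
                 alpha_bar_prev = alpha_bar_prev, beta_tilde = beta_tilde,
                 log_beta_tilde_clipped = lbt),
            class = "diffusion_schedule")
}

#' @export
print.diffusion_schedule <- function(x, ...) {
  cat(sprintf("<diffusion_schedule> %s, T = %d, alpha_bar_T = %.3g\n",
              x$kind, x$T_steps, x$alpha_bar[x$T_steps]))
  invisible(x)
}

check_t <- function(t, schedule) {
  if (any(t < 1L | t > schedule$T_steps)) {
    stopf("t out of range [1, %d]", schedule$T_steps)
  }
  as.integer(t)
}

#' Closed-form forward diffusion marginal
#'
#' Returns \eqn{x_t = \sqrt{\bar\alpha_t} x_0 + \sqrt{1 - \bar\alpha_t}
#' \epsilon}, the marginal obtained by composing the single-step Gaussian
#' corruption kernel t times.
#'
#' @param x0 Clean signal array (any shape).
#' @param t Timestep in `[1, T]`; scalar, or a vector indexing the last
#'   (batch) dimension of `x0`.
#' @param eps Noise array shaped like `x0`.
#' @param schedule A [make_schedule()] object.
#' @return Array shaped like `x0`.
#' @export
q_sample <- function(x0, t, eps, schedule) {
  t <- check_t(t, schedule)
  if (!identical(dim(x0), dim(eps)) && length(x0) != length(eps)) {
    stopf("`eps` must be shaped like `x0`")
  }
  ab <- schedule$alpha_bar[t]
  if (length(t) == 1L) {
    sqrt(ab) * x0 + sqrt(1 - ab) * eps
  } else {
    d <- dim(x0)
    per <- prod(d[-length(d)])
    a <- rep(sqrt(ab), each = per)
    b <- rep(sqrt(1 - ab), each = per)
    array(a * as.vector(x0) + b * as.vector(eps), d)
  }
}

#' Stepwise forward diffusion (test oracle)
#'
#' Applies the single-step corruption kernel
#' \eqn{x_t = \sqrt{1-\beta_t}\, x_{t-1} + \sqrt{\beta_t}\, \epsilon_t}
#' sequentially from \eqn{x_0}. This is the brute-force counterpart of
#' [q_sample()]'s closed form and exists to validate it; training and
#' sampling never use it.
#'
#' @param x0 Clean signal array.
#' @param t Number of steps to apply (scalar).
#' @param schedule A [make_schedule()] object.
#' @return Array shaped like `x0`.
#' @export
iterate_forward <- function(x0, t, schedule) {
  t <- check_t(t, schedule)
  stopifnot(length(t) == 1L)
  x <- x0
  for (s in seq_len(t)) {
    eps <- stats::rnorm(length(x))
    if (!is.null(dim(x))) dim(eps) <- dim(x)
    x <- sqrt(1 - schedule$beta[s]) * x + sqrt(schedule$beta[s]) * eps
  }
  x
}

#' Reverse-process moments from network outputs
#'
#' Converts the network's noise prediction and variance-interpolation
#' output into the mean and log-variance of the reverse Gaussian kernel:
#' \deqn{\mu_\theta = (x_t - \beta_t \epsilon_\theta / \sqrt{1-\bar\alpha_t})
#'   / \sqrt{\alpha_t},}
#' \deqn{\log \Sigma_\theta = v_\theta \log\beta_t +
#'   (1 - v_\theta) \log\tilde\beta_t,}
#' the log-linear interpolation between the two variance extremes. At
#' t = 1 the clipped \eqn{\log\tilde\beta} value is used (the exact
#' \eqn{\tilde\beta_1} is 0 and the final step is taken noiselessly).
#'
#' @param xt Noisy signal array.
#' @param t Timestep (scalar, or vector indexing the batch axis).
#' @param eps_pred Network noise prediction, shaped like `xt`.
#' @param v_pred Network variance coefficient in `[0, 1]`, shaped like `xt`.
#' @param schedule A [make_schedule()] object.
#' @return List with arrays `mu` and `log_var`.
#' @export
reverse_moments <- function(xt, t, eps_pred, v_pred, schedule) {
  t <- check_t(t, schedule)
  v_pred <- pmin(pmax(v_pred, 0), 1)
  bc <- function(v) {                        # broadcast per-batch scalar
    if (length(t) == 1L) v else {
      d <- dim(xt)
      array(rep(v, each = prod(d[-length(d)])), d)
    }
  }
  al <- bc(schedule$alpha[t])
  be <- bc(schedule$beta[t])
  ab <- bc(schedule$alpha_bar[t])
  lbt <- bc(schedule$log_beta_tilde_clipped[t])
  mu <- (xt - be / sqrt(1 - ab) * eps_pred) / sqrt(al)
  log_var <- v_pred * log(be) + (1 - v_pred) * lbt
  list(mu = mu, log_var = log_var)
}

## Gaussian posterior q(x_{t-1} | x_t, x_0): mean and variance
posterior_moments <- function(x0, xt, t, schedule) {
  bc_len <- length(t) > 1L
  bc <- function(v) {
    if (!bc_len) v else {
      d <- dim(xt)
      array(rep(v, each = prod(d[-length(d)])), d)
    }
  }
  ab <- bc(schedule$alpha_bar[t])
  abp <- bc(schedule$alpha_bar_prev[t])
  be <- bc(schedule$beta[t])
  al <- bc(schedule$alpha[t])
  mu <- sqrt(abp) * be / (1 - ab) * x0 + sqrt(al) * (1 - abp) / (1 - ab) * xt
  var <- (1 - abp) / (1 - ab) * be
  list(mu = mu, var = var)
}
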