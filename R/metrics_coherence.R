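## Wavelet coherence between signals, and the set-level 0-100 similarity
## score built on it.
##
## The continuous wavelet transform uses the analytic Morlet wavelet
## (omega0 = 6) evaluated in the frequency domain over a dyadic scale
## grid. Coherence is the smoothed normalized cross-spectrum
##   R^2 = |S(W_xy / s)|^2 / ( S(|W_x|^2 / s) * S(|W_y|^2 / s) ),
## with scale-dependent Gaussian smoothing in time and a boxcar over
## adjacent scales. Without smoothing single-realization coherence is
## identically 1, so smoothing is not optional.

cwt_scales <- function(n, dt = 1, s0 = 2 * dt, dj = 0.25) {
  J <- floor(log2(n * dt / s0) / dj)
  s0 * 2^(dj * (0:J))
}

## analytic Morlet CWT; returns (n_scales x n) complex matrix
cwt_morlet <- function(x, scales, dt = 1, omega0 = 6) {
  n <- length(x)
  npad <- 2^ceiling(log2(n))
  xp <- c(x - mean(x), rep(0, npad - n))
  xf <- stats::fft(xp)
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, k, k - npad) * (2 * pi / (npad * dt))
  W <- matrix(0i, length(scales), n)
  norm0 <- pi^(-1 / 4)
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi_hat <- numeric(npad)
    pos <- omega > 0
    psi_hat[pos] <- norm0 * sqrt(2 * pi * s / dt) *
      exp(-((s * omega[pos] - omega0)^2) / 2)
    w <- stats::fft(xf * psi_hat, inverse = TRUE) / npad
    W[j, ] <- w[seq_len(n)]
  }
  W
}

## Gaussian smoothing along time, bandwidth proportional to the scale
smooth_time <- function(M, scales, dt = 1) {
  out <- M
  n <- ncol(M)
  for (j in seq_len(nrow(M))) {
    s <- scales[j] / dt
    hw <- max(1L, min(n - 1L, ceiling(3 * s)))
    kk <- exp(-0.5 * ((-hw:hw) / s)^2)
    kk <- kk / sum(kk)
    row <- M[j, ]
    sm <- stats::convolve(c(Re(row), numeric(0)), rev(kk), type = "open")
    smi <- if (is.complex(row)) {
      stats::convolve(Im(row), rev(kk), type = "open")
    } else NULL
    idx <- hw + seq_len(n)
    out[j, ] <- if (is.null(smi)) sm[idx] else complex(real = sm[idx],
                                                       imaginary = smi[idx])
  }
  out
}

## boxcar smoothing across adjacent scales (width ~ 0.6/dj)
smooth_scale <- function(M, dj = 0.25) {
  w <- max(1L, round(0.6 / dj / 2))
  ns <- nrow(M)
  out <- M
  for (j in seq_len(ns)) {
    lo <- max(1L, j - w); hi <- min(ns, j + w)
    out[j, ] <- colMeans(M[lo:hi, , drop = FALSE])
  }
  out
}

smooth_op <- function(M, scales, dt, dj) {
  smooth_scale(smooth_time(M, scales, dt), dj)
}

#' Wavelet coherence map of two signals
#'
#' Computes the time-scale coherence between two equal-length,
#' single-channel signals: the squared magnitude of the smoothed
#' cross-wavelet spectrum divided by the product of the smoothed power
#' spectra, clipped to `[0, 1]`. A value of 1 means the signals oscillate
#' in synchrony at that time and scale. Constant (zero-power) inputs have
#' no defined phase relationship; the map is set to 0 with a warning.
#'
#' @param x,y Numeric vectors of equal length.
#' @param dt Sampling interval (time units per step).
#' @param dj Scale resolution (octave fraction per scale step).
#' @param omega0 Morlet center frequency (default 6).
#' @return A `coherence_map`: list with `values` (scales x time, in
#'   `[0, 1]`), `scales`, `times`.
#' @export
wavelet_coherence_pair <- function(x, y, dt = 1, dj = 0.25, omega0 = 6) {
  if (length(x) != length(y)) stopf("signals must have equal length")
  n <- length(x)
  scales <- cwt_scales(n, dt, dj = dj)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant signal: coherence defined as 0")
    return(structure(list(values = matrix(0, length(scales), n),
                          scales = scales, times = seq_len(n) * dt),
                     class = "coherence_map"))
  }
  Wx <- cwt_morlet(x, scales, dt, omega0)
  Wy <- cwt_morlet(y, scales, dt, omega0)
  inv_s <- 1 / scales
  Sxx <- Re(smooth_op((Mod(Wx)^2) * inv_s, scales, dt, dj))
  Syy <- Re(smooth_op((Mod(Wy)^2) * inv_s, scales, dt, dj))
  Sxy <- smooth_op(Wx * Conj(Wy) * inv_s, scales, dt, dj)
  r2 <- Mod(Sxy)^2 / pmax(Sxx * Syy, 1e-300)
  r2 <- pmin(pmax(r2, 0), 1)
  structure(list(values = r2, scales = scales, times = seq_len(n) * dt),
            class = "coherence_map")
}

## mean coherence of one (possibly multichannel) signal pair
pair_mean_coherence <- function(xi, yi) {
  C <- nrow(xi)
  mean(vapply(seq_len(C), function(ch) {
    mean(wavelet_coherence_pair(xi[ch, ], yi[ch, ])$values)
  }, numeric(1)))
}

#' Set-level wavelet coherence score
#'
#' Measures the similarity of two signal sets on a 0-100 scale: random
#' (or matched-index) pairs are drawn across the sets, the coherence map
#' of each pair is averaged over time and scale (and channels), and the
#' score is 100 times the mean over pairs. Identical sets compared with
#' identity pairing score 100.
#'
#' @param real,synth [signal_set()] objects with equal channel count and
#'   length.
#' @param n_pairs Number of random pairs drawn (capped by default at
#'   1000 for tractability).
#' @param seed Seed for the pair draw.
#' @param pairing `"random"` (default) or `"identity"` (pair i with i;
#'   requires equal set sizes).
#' @return A `coherence_report`: list with `score` (0-100), `n_pairs`,
#'   `per_pair`.
#' @export
set_coherence_score <- function(real, synth, n_pairs = 1000, seed = 1,
                                pairing = c("random", "identity")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(real, "signal_set"), inherits(synth, "signal_set"))
  nr <- n_signals(real); ns <- n_signals(synth)
  if (nr == 0 || ns == 0) stopf("empty signal set")
  if (!identical(dim(real$values)[-1], dim(synth$values)[-1])) {
    stopf("sets must share channel count and length")
  }
  ## cache per-signal smoothed auto-spectra and raw transforms so each
  ## signal's CWT is computed once, not once per pair
  prep <- function(set) {
    d <- dim(set$values)
    scales <- cwt_scales(d[3])
    lapply(seq_len(d[1]), function(i) {
      lapply(seq_len(d[2]), function(ch) {
        x <- set$values[i, ch, ]
        if (stats::sd(x) == 0) return(NULL)
        W <- cwt_morlet(x, scales)
        list(W = W,
             S = Re(smooth_op((Mod(W)^2) / scales, scales, 1, 0.25)),
             scales = scales)
      })
    })
  }
  pr <- prep(real); ps <- prep(synth)
  if (pairing == "identity") {
    if (nr != ns) stopf("identity pairing needs equal set sizes")
    ii <- seq_len(nr); jj <- seq_len(nr)
    n_pairs <- nr
  } else {
    pick <- with_seed(seed, {
      list(i = sample.int(nr, n_pairs, replace = TRUE),
           j = sample.int(ns, n_pairs, replace = TRUE))
    })
    ii <- pick$i; jj <- pick$j
  }
  per_pair <- vapply(seq_len(n_pairs), function(p) {
    a <- pr[[ii[p]]]; b <- ps[[jj[p]]]
    mean(vapply(seq_along(a), function(ch) {
      if (is.null(a[[ch]]) || is.null(b[[ch]])) return(0)
      sc <- a[[ch]]$scales
      Sxy <- smooth_op(a[[ch]]$W * Conj(b[[ch]]$W) / sc, sc, 1, 0.25)
      r2 <- Mod(Sxy)^2 / pmax(a[[ch]]$S * b[[ch]]$S, 1e-300)
      mean(pmin(pmax(r2, 0), 1))
    }, numeric(1)))
  }, numeric(1))
  structure(list(score = 100 * mean(per_pair), n_pairs = n_pairs,
                 per_pair = per_pair),
            class = "coherence_report")
}

#' @export
print.coherence_report <- function(x, ...) {
  cat(sprintf("<coherence_report> score %.2f / 100 over %d pairs\n",
              x$score, x$n_pairs))
  invisible(x)
}
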