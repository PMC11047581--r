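#' Simulation configuration for the cylinder-bell-funnel generator
#'
#' The simulated dataset is built from the classical cylinder-bell-funnel
#' (CBF) family: each signal is a baseline with one or two "events" whose
#' shape defines the class. Five classes are available: cylinder (plateau),
#' bell (linear rise then drop), funnel (jump then linear decay), a
#' bell-then-funnel composite, and a two-cylinder composite. Class
#' differences are controlled by the event shape; within-class variability
#' comes from the event amplitude (drawn from a normal distribution), from
#' Gaussian jitter of the event onset/offset, and from additive white noise.
#' Defaults follow the classical CBF construction: amplitude ~ N(6, 1),
#' unit-variance additive noise.
#'
#' @param n_per_class Signals generated per class.
#' @param length Timesteps per signal (default 512, minimum 16).
#' @param n_channels Channels per signal (default 1). Channels share the
#'   event structure and amplitude; noise is drawn independently.
#' @param n_classes Number of classes, between 1 and 5.
#' @param amp_mean Mean event amplitude (amplitude units).
#' @param amp_var Variance of the event amplitude.
#' @param pattern_var Variance (in squared timesteps) of the Gaussian
#'   jitter applied to event onsets/offsets.
#' @param noise_sd Standard deviation of the additive white noise.
#' @param seed RNG seed for the generator.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_class = 20, length = 512, n_channels = 1,
                       n_classes = 5, amp_mean = 6, amp_var = 1,
                       pattern_var = 100, noise_sd = 1, seed = 1) {
  if (length < 16) stopf("`length` must be >= 16 (got %d)", length)
  if (n_classes < 1 || n_classes > 5) {
    stopf("`n_classes` must be in [1, 5] (got %s)", n_classes)
  }
  if (amp_var < 0 || pattern_var < 0 || noise_sd < 0) {
    stopf("variances and noise_sd must be >= 0")
  }
  if (n_per_class < 1) stopf("`n_per_class` must be >= 1")
  structure(list(n_per_class = as.integer(n_per_class),
                 length = as.integer(length),
                 n_channels = as.integer(n_channels),
                 n_classes = as.integer(n_classes),
                 amp_mean = amp_mean, amp_var = amp_var,
                 pattern_var = pattern_var, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Nominal event windows per class, as fractions of the signal length.
## Jitter (pattern_var) perturbs the window edges around these.
cbf_windows <- function(class) {
  switch(as.character(class),
         "0" = list(c(0.25, 0.65)),            # cylinder
         "1" = list(c(0.25, 0.65)),            # bell
         "2" = list(c(0.25, 0.65)),            # funnel
         "3" = list(c(0.12, 0.44), c(0.56, 0.88)),  # bell then funnel
         "4" = list(c(0.12, 0.36), c(0.56, 0.82)),  # two cylinders
         stopf("unknown class %s", class))
}

## One event segment of the requested shape over samples a..b (inclusive).
cbf_event <- function(shape, a, b, amp) {
  n <- b - a + 1L
  switch(shape,
         cylinder = rep(amp, n),
         bell     = amp * seq(0, 1, length.out = n),  # ramp up, abrupt drop
         funnel   = amp * seq(1, 0, length.out = n),  # jump, linear decay
         stopf("unknown shape %s", shape))
}

cbf_shapes <- function(class) {
  switch(as.character(class),
         "0" = "cylinder",
         "1" = "bell",
         "2" = "funnel",
         "3" = c("bell", "funnel"),
         "4" = c("cylinder", "cylinder"))
}

#' Noiseless class template
#'
#' The template of a class is its signal with zero amplitude variance, zero
#' boundary jitter, and zero additive noise; it is the per-class mean shape
#' used by recovery checks.
#'
#' @param class Class code 0..4.
#' @param length Timesteps.
#' @param amp_mean Event amplitude.
#' @return Numeric vector of length `length`.
#' @export
cbf_template <- function(class, length, amp_mean = 6) {
  x <- numeric(length)
  wins <- cbf_windows(class)
  shp <- cbf_shapes(class)
  for (i in seq_along(wins)) {
    a <- max(1L, round(wins[[i]][1] * length))
    b <- min(length, round(wins[[i]][2] * length))
    x[a:b] <- x[a:b] + cbf_event(shp[i], a, b, amp_mean)
  }
  x
}

#' Generate the simulated CBF dataset
#'
#' Produces `n_classes * n_per_class` labelled signals. Each signal is the
#' class template with jittered event boundaries, a random event amplitude,
#' and additive white noise (see [sim_config()]).
#'
#' @param config A [sim_config()].
#' @return A [signal_set()] with 0-based labels `0..n_classes-1`.
#' @export
generate_simulated <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  n <- cf$n_classes * cf$n_per_class
  vals <- array(0, c(n, cf$n_channels, cf$length))
  labels <- integer(n)
  with_seed(cf$seed, {
    i <- 0L
    for (cls in seq_len(cf$n_classes) - 1L) {
      wins <- cbf_windows(cls)
      shp <- cbf_shapes(cls)
      for (r in seq_len(cf$n_per_class)) {
        i <- i + 1L
        labels[i] <- cls
        amp <- stats::rnorm(1, cf$amp_mean, sqrt(cf$amp_var))
        base <- numeric(cf$length)
        for (w in seq_along(wins)) {
          a0 <- round(wins[[w]][1] * cf$length)
          b0 <- round(wins[[w]][2] * cf$length)
          jit <- round(stats::rnorm(2, 0, sqrt(cf$pattern_var)))
          a <- max(1L, min(cf$length - 2L, a0 + jit[1]))
          b <- max(a + 1L, min(cf$length, b0 + jit[2]))
          base[a:b] <- base[a:b] + cbf_event(shp[w], a, b, amp)
        }
        for (ch in seq_len(cf$n_channels)) {
          vals[i, ch, ] <- base +
            if (cf$noise_sd > 0) stats::rnorm(cf$length, 0, cf$noise_sd) else 0
        }
      }
    }
  })
  signal_set(vals, labels = labels)
}

#' Degradation specification
#'
#' Describes one of five corruption models applied by [degrade()]:
#' `thermal` (additive white Gaussian noise), `baseline_wander` (additive
#' low-frequency sinusoidal drift, modelling electrode-contact noise),
#' `motion_artifact` (sparse spikes of width 1-3 samples), `mask_gaps`
#' (contiguous zeroed gaps with an observation mask), and `downsample`
#' (decimate then linearly interpolate back to the original length, so the
#' degraded signal keeps the original dimensions).
#'
#' @param kind One of `"thermal"`, `"baseline_wander"`, `"motion_artifact"`,
#'   `"mask_gaps"`, `"downsample"`.
#' @param magnitude Kind-specific scale: noise sd (thermal), drift amplitude
#'   (baseline_wander), mean spike amplitude (motion_artifact). Ignored for
#'   mask_gaps/downsample.
#' @param gap_fraction Fraction of each signal masked (mask_gaps only),
#'   in `[0, 1)`.
#' @param factor Integer decimation factor >= 2 (downsample only).
#' @param seed RNG seed.
#' @return A `degradation_spec` list.
#' @export
degradation_spec <- function(kind = c("thermal", "baseline_wander",
                                      "motion_artifact", "mask_gaps",
                                      "downsample"),
                             magnitude = 0.1, gap_fraction = 0.25,
                             factor = 2, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "mask_gaps" && (gap_fraction < 0 || gap_fraction >= 1)) {
    stopf("`gap_fraction` must be in [0, 1)")
  }
  if (kind == "downsample" && (factor < 2 || factor != round(factor))) {
    stopf("`factor` must be an integer >= 2")
  }
  if (magnitude < 0) stopf("`magnitude` must be >= 0")
  structure(list(kind = kind, magnitude = magnitude,
                 gap_fraction = gap_fraction, factor = as.integer(factor),
                 seed = as.integer(seed)),
            class = "degradation_spec")
}

## contiguous gap layout covering exactly n_gap samples of L, as a 0/1
## observation vector (1 = observed); gaps split into 1..3 runs
gap_mask_vector <- function(L, n_gap) {
  if (n_gap <= 0) return(rep(1L, L))
  g <- sample.int(min(3L, n_gap), 1L)
  # split n_gap into g positive parts
  if (g > 1L) {
    cuts <- sort(sample.int(n_gap - 1L, g - 1L))
    parts <- diff(c(0L, cuts, n_gap))
  } else parts <- n_gap
  free <- L - n_gap
  # distribute free space around the g runs (g+1 slots)
  slot <- if (free > 0) as.vector(stats::rmultinom(1, free, rep(1, g + 1L))) else rep(0L, g + 1L)
  m <- rep(1L, L)
  pos <- 0L
  for (i in seq_len(g)) {
    pos <- pos + slot[i]
    m[(pos + 1L):(pos + parts[i])] <- 0L
    pos <- pos + parts[i]
  }
  m
}

#' Apply a degradation model to a signal set
#'
#' Output always has the same shape as the input. For `mask_gaps` the
#' returned mask marks observed samples with 1; masked samples are zeroed.
#' For `downsample`, every `factor`-th sample is kept and the signal is
#' resized back to full length by linear interpolation.
#'
#' @param signals A [signal_set()].
#' @param spec A [degradation_spec()].
#' @return A list with elements `signals` (degraded [signal_set()]) and
#'   `mask` (binary array shaped like `values` for `mask_gaps`, else `NULL`).
#' @export
degrade <- function(signals, spec) {
  stopifnot(inherits(signals, "signal_set"), inherits(spec, "degradation_spec"))
  v <- signals$values
  d <- dim(v)
  n <- d[1]; C <- d[2]; L <- d[3]
  mask <- NULL
  out <- with_seed(spec$seed, {
    switch(spec$kind,
      thermal = {
        if (spec$magnitude > 0) {
          v + array(stats::rnorm(length(v), 0, spec$magnitude), d)
        } else v
      },
      baseline_wander = {
        if (spec$magnitude == 0) v else {
          tt <- seq_len(L)
          for (i in seq_len(n)) for (ch in seq_len(C)) {
            k <- sample.int(3L, 1L)
            w <- stats::runif(k); w <- w / sum(w)
            drift <- numeric(L)
            for (j in seq_len(k)) {
              period <- stats::runif(1, L / 4, 2 * L)
              phase <- stats::runif(1, 0, 2 * pi)
              drift <- drift +
                spec$magnitude * w[j] * sin(2 * pi * tt / period + phase)
            }
            v[i, ch, ] <- v[i, ch, ] + drift
          }
          v
        }
      },
      motion_artifact = {
        if (spec$magnitude == 0) v else {
          for (i in seq_len(n)) for (ch in seq_len(C)) {
            n_spk <- stats::rpois(1, 5)
            if (n_spk > 0) {
              for (s in seq_len(n_spk)) {
                amp <- sample(c(-1, 1), 1) *
                  abs(stats::rnorm(1, spec$magnitude, spec$magnitude / 4))
                wd <- sample.int(3L, 1L)
                at <- sample.int(L - wd + 1L, 1L)
                v[i, ch, at:(at + wd - 1L)] <- v[i, ch, at:(at + wd - 1L)] + amp
              }
            }
          }
          v
        }
      },
      mask_gaps = {
        n_gap <- round(spec$gap_fraction * L)
        mask <- array(1L, d)
        for (i in seq_len(n)) {
          mv <- gap_mask_vector(L, n_gap)
          for (ch in seq_len(C)) {
            mask[i, ch, ] <- mv
            v[i, ch, ] <- v[i, ch, ] * mv
          }
        }
        v
      },
      downsample = {
        if (spec$factor >= L) stopf("downsample factor must be < length")
        keep <- seq(1L, L, by = spec$factor)
        for (i in seq_len(n)) for (ch in seq_len(C)) {
          v[i, ch, ] <- stats::approx(keep, v[i, ch, keep], xout = seq_len(L),
                                      rule = 2)$y
        }
        v
      })
  })
  list(signals = signal_set(out, labels = signals$labels,
                            channel_names = signals$channel_names),
       mask = mask)
}

#' Subsample classes to an imbalanced dataset
#'
#' @param signals Labelled [signal_set()].
#' @param keep_fractions Named or ordered numeric vector of per-class keep
#'   fractions in `(0, 1]`, one per class present (in sorted class order).
#' @param seed RNG seed.
#' @return A [signal_set()] with each class subsampled without replacement.
#' @export
make_imbalanced <- function(signals, keep_fractions, seed = 1) {
  stopifnot(inherits(signals, "signal_set"))
  if (is.null(signals$labels)) stopf("signals must be labelled")
  classes <- sort(unique(signals$labels))
  if (length(keep_fractions) != length(classes)) {
    stopf("need one keep fraction per class (%d classes)", length(classes))
  }
  if (any(keep_fractions <= 0 | keep_fractions > 1)) {
    stopf("keep fractions must be in (0, 1]")
  }
  idx <- with_seed(seed, {
    unlist(lapply(seq_along(classes), function(i) {
      ci <- which(signals$labels == classes[i])
      m <- max(1L, round(keep_fractions[i] * length(ci)))
      if (m < 1) stopf("class %s would become empty", classes[i])
      sort(sample(ci, m))
    }))
  })
  subset_signals(signals, idx)
}
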