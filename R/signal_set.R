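#' Construct a signal set
#'
#' A signal set is the package's basic container: a batch of multichannel
#' time series stored as a numeric array of dimension
#' `(n_samples, n_channels, n_timesteps)`, with optional integer class
#' labels (one per sample) and optional channel names. It plays the role
#' of the clean data \eqn{x_0} everywhere in the diffusion machinery.
#'
#' @param values Numeric array `(n_samples, n_channels, n_timesteps)`.
#'   A matrix `(n_samples, n_timesteps)` is promoted to one channel.
#' @param labels Optional integer vector of length `n_samples`
#'   (0-based class codes).
#' @param channel_names Optional character vector, one name per channel.
#' @return An object of class `signal_set`.
#' @export
signal_set <- function(values, labels = NULL, channel_names = NULL) {
  if (is.matrix(values)) {
    values <- array(values, c(nrow(values), 1L, ncol(values)))
  }
  if (!is.array(values) || length(dim(values)) != 3L) {
    stopf("`values` must be a 3D array (n_samples, n_channels, n_timesteps)")
  }
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values))
    stopf("`values` contains %d non-finite entries (first index %d)",
          length(bad), bad[1])
  }
  if (!is.null(labels)) {
    if (length(labels) != dim(values)[1]) {
      stopf("labels length (%d) != n_samples (%d)",
            length(labels), dim(values)[1])
    }
    labels <- as.integer(labels)
  }
  if (!is.null(channel_names) && length(channel_names) != dim(values)[2]) {
    stopf("channel_names length != n_channels")
  }
  structure(list(values = values, labels = labels,
                 channel_names = channel_names),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<signal_set> %d samples x %d channels x %d timesteps\n",
              d[1], d[2], d[3]))
  if (!is.null(x$labels)) {
    tb <- table(x$labels)
    cat("  labels:", paste(sprintf("%s:%d", names(tb), tb), collapse = " "), "\n")
  }
  invisible(x)
}

#' Number of samples in a signal set
#' @param x A `signal_set`.
#' @return Integer count.
#' @export
n_signals <- function(x) {
  stopifnot(inherits(x, "signal_set"))
  dim(x$values)[1]
}

#' Subset a signal set by sample index
#' @param x A `signal_set`.
#' @param idx Integer sample indices (1-based).
#' @return A `signal_set` with the selected samples.
#' @export
subset_signals <- function(x, idx) {
  stopifnot(inherits(x, "signal_set"))
  signal_set(x$values[idx, , , drop = FALSE],
             labels = if (!is.null(x$labels)) x$labels[idx],
             channel_names = x$channel_names)
}

#' Concatenate signal sets along the sample axis
#' @param ... `signal_set` objects with matching channel/timestep dims.
#' @return A combined `signal_set`.
#' @export
bind_signals <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  d <- dim(sets[[1]]$values)[-1]
  for (s in sets) {
    if (!identical(dim(s$values)[-1], d)) stopf("incompatible signal dimensions")
  }
  vals <- do.call(abind3, lapply(sets, function(s) s$values))
  labs <- lapply(sets, function(s) s$labels)
  labels <- if (all(!vapply(labs, is.null, logical(1)))) unlist(labs) else NULL
  signal_set(vals, labels = labels, channel_names = sets[[1]]$channel_names)
}

## rbind for 3D arrays along the first axis
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

## internal layout change: (n, C, L) -> (C, L, B) used by the network code
ss_to_clb <- function(values) aperm(values, c(2, 3, 1))
clb_to_ss <- function(x) aperm(x, c(3, 1, 2))
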