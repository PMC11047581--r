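#' Joint UMAP overlay of a real and a synthetic set
#'
#' Flattens every signal into a feature vector (channels x timesteps),
#' fits a single UMAP embedding on the concatenation of both sets, and
#' returns the 2D coordinates tagged by origin. Co-locating clusters of
#' real and synthetic points indicate distributional similarity. A
#' two-color scatter plot is optionally written as PNG.
#'
#' The embedding is computed by the UMAP reference implementation
#' (`umap-learn`), invoked through the `python` interpreter on the PATH;
#' coordinates are deterministic for a fixed seed.
#'
#' @param real,synth [signal_set()] objects.
#' @param n_neighbors UMAP neighborhood size (auto-shrunk with a warning
#'   when the sets are smaller).
#' @param min_dist UMAP minimum embedding distance.
#' @param seed Random state passed to UMAP.
#' @param plot_file Optional path of a PNG scatter plot to write.
#' @return Data frame with columns `sample_id`, `origin` ("real" or
#'   "synthetic"), `dim1`, `dim2`.
#' @export
umap_overlay <- function(real, synth, n_neighbors = 15, min_dist = 0.1,
                         seed = 1, plot_file = NULL) {
  stopifnot(inherits(real, "signal_set"), inherits(synth, "signal_set"))
  nr <- n_signals(real); ns <- n_signals(synth)
  if (nr == 0 || ns == 0) stopf("empty signal set")
  flat <- function(s) {
    d <- dim(s$values)
    matrix(s$values, d[1], d[2] * d[3])
  }
  X <- rbind(flat(real), flat(synth))
  n <- nrow(X)
  if (n_neighbors >= n) {
    warning(sprintf("n_neighbors reduced from %d to %d (small sets)",
                    n_neighbors, n - 1L))
    n_neighbors <- n - 1L
  }
  py <- Sys.which("python")
  if (py == "") stopf("no `python` interpreter on PATH (needed for UMAP)")
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(X, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- system.file("python", "umap_embed.py", package = "sigdiffuse")
  if (script == "") script <- file.path("inst", "python", "umap_embed.py")
  rc <- system2(py, c(script, fin, fout, n_neighbors,
                      format(min_dist, scientific = FALSE), seed),
                stdout = FALSE, stderr = "")
  if (rc != 0 || !file.exists(fout)) stopf("UMAP embedding failed (exit %d)", rc)
  co <- utils::read.csv(fout, header = FALSE)
  out <- data.frame(sample_id = seq_len(n),
                    origin = c(rep("real", nr), rep("synthetic", ns)),
                    dim1 = co[[1]], dim2 = co[[2]])
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 700, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    cols <- ifelse(out$origin == "real", "#1f77b4", "#d62728")
    graphics::plot(out$dim1, out$dim2, col = cols, pch = 19, cex = 0.7,
                   xlab = "UMAP 1", ylab = "UMAP 2",
                   main = "Real vs synthetic signals (joint UMAP)")
    graphics::legend("topright", legend = c("real", "synthetic"),
                     col = c("#1f77b4", "#d62728"), pch = 19)
  }
  out
}
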