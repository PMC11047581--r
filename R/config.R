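#' Run configuration
#'
#' Bundles everything one pipeline run needs: the operating mode, the
#' simulator settings, the training and network settings, metric
#' parameters, file paths, and a single global seed that fans out to the
#' per-module generators with fixed offsets (so every stage is
#' independently reproducible).
#'
#' @param mode `"uncond"`, `"label"`, or `"signal"`.
#' @param sim A [sim_config()].
#' @param train A [train_config()].
#' @param unet Optional [unet_config()] (defaults are derived from data).
#' @param metrics Named list of metric parameters (`n_pairs`,
#'   `n_neighbors`, `min_dist`).
#' @param paths Named list of input/output locations.
#' @param seed Global seed.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = "uncond", sim = sim_config(),
                       train = train_config(), unet = NULL,
                       metrics = list(n_pairs = 1000, n_neighbors = 15,
                                      min_dist = 0.1),
                       paths = list(), seed = 1) {
  if (!mode %in% c("uncond", "label", "signal")) stopf("bad mode %s", mode)
  structure(list(mode = mode, sim = sim, train = train, unet = unet,
                 metrics = metrics, paths = paths, seed = as.integer(seed)),
            class = "run_config")
}

.rc_known <- c("mode", "sim", "train", "unet", "metrics", "paths", "seed")

#' Write a run configuration to YAML
#' @param config A [run_config()].
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  yaml::write_yaml(strip(unclass(config)), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Unknown top-level keys are rejected; known blocks are rebuilt through
#' their constructors so invariants are re-validated.
#'
#' @param path YAML path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .rc_known)
  if (length(unknown)) stopf("unknown config keys: %s",
                             paste(unknown, collapse = ", "))
  sim <- if (!is.null(raw$sim)) do.call(sim_config, raw$sim) else sim_config()
  tr_args <- raw$train
  if (!is.null(tr_args$ema_decay) && identical(tr_args$ema_decay, "NULL")) {
    tr_args$ema_decay <- NULL
  }
  train <- if (!is.null(tr_args)) do.call(train_config, tr_args)
           else train_config()
  unet <- if (!is.null(raw$unet)) do.call(unet_config, raw$unet)
  run_config(mode = raw$mode %||% "uncond", sim = sim, train = train,
             unet = unet, metrics = raw$metrics %||%
               list(n_pairs = 1000, n_neighbors = 15, min_dist = 0.1),
             paths = raw$paths %||% list(), seed = raw$seed %||% 1)
}

#' Save / load a diffusion model checkpoint
#'
#' The checkpoint is a single RDS archive holding the network weights,
#' schedule tables, configurations, normalization statistics, mode tag,
#' and training history.
#'
#' @param fit A `diffusion_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: the
#'   `diffusion_model`.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "diffusion_model"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "diffusion_model")) stopf("not a checkpoint: %s", path)
  fit
}
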