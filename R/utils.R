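#' @keywords internal
"_PACKAGE"

## Run code under a temporary RNG state so package operations are
## reproducible from their own `seed` arguments without clobbering the
## caller's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Derive independent sub-seeds from one global seed with fixed offsets,
## so each module's stream is reproducible on its own. Kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

log_msg <- function(level, fmt, ..., file = NULL) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, sprintf(fmt, ...))
  message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
  invisible(line)
}
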