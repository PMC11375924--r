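#' @keywords internal
"_PACKAGE"

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so that seeded helpers do not perturb surrounding streams.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

msync_abort <- function(..., class = "microsync_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Structured progress/log line on stderr; silenced via option.
msync_log <- function(...) {
  if (isTRUE(getOption("microsync.quiet", FALSE))) {
    return(invisible())
  }
  message("[microsync] ", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
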