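# Structured error conditions. Three families map onto the CLI exit-status
# contract: usage errors (bad flags/zoom syntax) -> 2, data errors (bad input
# file content, out-of-range positions) -> 1, config errors (broken
# installation) -> 1.

cg_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cg_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = NULL)
  ))
}

usage_error  <- function(msg, ...) cg_stop("cg_usage_error", msg, ...)
data_error   <- function(msg, ...) cg_stop("cg_data_error", msg, ...)
parse_error  <- function(msg, ...) cg_stop(c("cg_parse_error", "cg_data_error"), msg, ...)
config_error <- function(msg, ...) cg_stop("cg_config_error", msg, ...)

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never disturb user-level randomness.
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
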