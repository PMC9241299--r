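# Shared internal helpers.

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Error class used by the CLI to distinguish bad input (exit 2) from
# runtime failure (exit 1).
input_error <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c("icrscan_input_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
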