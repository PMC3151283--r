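# Internal helpers: classed error conditions and scoped RNG.

stop_data <- function(msg) {
  stop(structure(
    class = c("frapkit_data_error", "frapkit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_config <- function(msg) {
  stop(structure(
    class = c("frapkit_config_error", "frapkit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream; all generators route through this so identical seeds give
# bit-identical output regardless of surrounding code.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
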