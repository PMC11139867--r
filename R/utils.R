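# Internal helpers shared across modules.

# Classed error so callers can distinguish failure modes programmatically.
fk_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "fluctkin_error")))
}

fk_warn <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...),
                           class = c(class, "fluctkin_warning")))
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# seed = NULL draws from the current stream (used for nested generators that
# are already running under a master seed).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
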