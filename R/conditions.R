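# Structured error conditions used across the package.
#
# Three classes are distinguished so callers can react programmatically:
#   opercal_invalid_argument - the caller passed something malformed
#   opercal_empty_result     - a valid call had nothing to compute on
#   opercal_undefined        - a statistic is mathematically undefined here

stop_invalid <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("opercal_invalid_argument", "error")))
}

stop_empty <- function(msg) {
  stop(errorCondition(msg, class = c("opercal_empty_result", "error")))
}

stop_undefined <- function(msg) {
  stop(errorCondition(msg, class = c("opercal_undefined", "error")))
}

# Scalar-argument checks --------------------------------------------------

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_invalid(sprintf("`%s` must be a positive scalar, got %s",
                         name, deparse(substitute(x))))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop_invalid(sprintf("`%s` must be an integer >= %d", name, min))
  as.integer(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Keeps simulator streams independent of the
# session RNG and of each other.
with_seed <- function(seed, expr) {
  seed <- check_count(seed, "seed", min = 0L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
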