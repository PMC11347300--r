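#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the random seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded helpers do not perturb the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Derive reproducible child seeds from a master seed
#'
#' @param seed Master seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` distinct seeds in `[1, 2^31 - 1]`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# stop() with a consistent "field: problem" message for config validation
config_stop <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

check_count <- function(value, field, min = 1L) {
  if (length(value) != 1L || !is.finite(value) || value != round(value) ||
      value < min) {
    config_stop(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(value)
}

check_duration <- function(value, field, allow_zero = FALSE) {
  lo <- if (allow_zero) 0 else .Machine$double.eps
  if (length(value) != 1L || !is.finite(value) || value < lo) {
    config_stop(field, if (allow_zero) "must be a nonnegative duration" else
      "must be a positive duration")
  }
  as.numeric(value)
}
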