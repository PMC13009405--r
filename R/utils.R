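#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a local RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded generators never disturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed from a master seed; keeps values in 32-bit range
child_seed <- function(seed, offset) {
  (abs(as.integer(seed)) %% 20000L) * 100000L + abs(as.integer(offset)) %% 100000L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop_invalid(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_invalid(sprintf("`%s` must be a probability in [0, 1]", name))
  as.numeric(x)
}
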