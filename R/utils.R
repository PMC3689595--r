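`%||%` <- function(x, y) if (is.null(x)) y else x

abort <- function(...) stop(..., call. = FALSE)

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded at `seed`, then restores the caller's RNG
#' state, so seeded analysis steps do not perturb the global random stream.
#' With `seed = NULL` the expression runs against the current stream.
#'
#' @param seed integer seed or NULL.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

## stable sprintf-style id padding
pad_id <- function(prefix, i, width = 6) sprintf("%s%0*d", prefix, width, i)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
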