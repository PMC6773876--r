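# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals never
#' disturb the caller's random number stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed from a master seed and an index; kept within
# the 32-bit signed integer range R requires of set.seed().
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + 7919 * as.double(index)) %% 2147483647)
}

stop_input <- function(...) stop(..., call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

assert_probability <- function(p, what = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop_input(what, " must be in [0, 1]")
  invisible(p)
}
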