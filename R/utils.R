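#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators and heuristics are reproducible without
#' clobbering the global stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopifnot_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
    stop(sprintf("%s must be numeric in [0, 1]", what), call. = FALSE)
  invisible(x)
}

stopifnot_scalar_count <- function(x, what, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop(sprintf("%s must be a single integer >= %s", what, min),
         call. = FALSE)
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Convenience wrapper used for planted-structure recovery metrics.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' Precision/recall of a predicted set against a truth set
#' @param predicted,truth character vectors of ids.
#' @return named numeric vector with `precision` and `recall`.
#' @export
set_recovery <- function(predicted, truth) {
  tp <- length(intersect(predicted, truth))
  c(precision = if (length(predicted)) tp / length(predicted) else NA_real_,
    recall = if (length(truth)) tp / length(truth) else NA_real_)
}

# canonical (sorted) undirected pair keys
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
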