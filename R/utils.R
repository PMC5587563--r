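# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero, the
#' convention used for the retained edge count at a given edge density.
#' (Base `round()` rounds half to even, which would give 598 instead of
#' 599 for 598.5.)
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
round_half_up <- function(x) {
  # guard against ties landing just below .5 in floating point
  # (e.g. 0.95 * 630 evaluates to 598.4999...)
  as.integer(sign(x) * floor(round(abs(x), 6) + 0.5))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL runs unseeded.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from a master seed; keeps values in the
# 32-bit signed integer range.
derive_seed <- function(master, counter) {
  if (is.null(master)) return(NULL)
  as.integer((as.double(master) * 48271 + as.double(counter)) %% 2147483647L)
}

stopifnot_square <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("%s must be a square matrix", what), call. = FALSE)
}

check_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m))))
    stop(sprintf("%s must be symmetric", what), call. = FALSE)
}

# Upper-triangle (i < j) index pairs of an n x n matrix, in column-major
# order, as a 2-column matrix. Used for deterministic edge bookkeeping.
upper_pairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), , drop = FALSE]
}
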