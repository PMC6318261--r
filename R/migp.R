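#' Incremental groupwise PCA over the target dimension (MIGP)
#'
#' Reduces a seeds x targets matrix to a seeds x `d` matrix whose column space
#' approximates the span of the top-`d` left singular vectors of the full
#' matrix, without ever holding more than `d + b` columns in memory. Target
#' columns are visited in random blocks of size at most `b`; at each step the
#' current working matrix (left singular vectors weighted by their singular
#' values) is concatenated with the next block and truncated back to rank `d`
#' by an economy SVD, until every target column has been consumed exactly
#' once.
#'
#' @param matrix A [connectivity_matrix()].
#' @param d Retained dimension (the analysis of full-size data uses 4000).
#' @param b Block size, must be >= `d` (full-size analyses use 10,000).
#' @param rng_seed Integer seed controlling the random block partition.
#' @return An object of class `tractica_reduced` with fields `values`
#'   (`n_seeds x d`), `d`, `b`, `visit_order` and `rng_seed`.
#' @export
migp_reduce <- function(matrix, d, b, rng_seed = 1L) {
  stopifnot(inherits(matrix, "tractica_connmat"))
  X <- dense_values(matrix)
  n <- nrow(X); m <- ncol(X)
  if (n == 0L || m == 0L) stop("empty matrix")
  if (d < 1L || b < 1L) stop("d and b must be >= 1")
  if (d > min(n, m))
    stop("d = ", d, " exceeds min(n_seeds, n_targets) = ", min(n, m))
  if (min(b, m) < d)
    stop("block size b = ", b, " smaller than d = ", d,
         ": working width would fall below the retained dimension")
  migp_reduce_raw(X, d, b, rng_seed)
}

#' @export
print.tractica_reduced <- function(x, ...) {
  cat("<tractica_reduced> ", nrow(x$values), " seeds x d=", x$d,
      " (block size b=", x$b, ", ", length(x$visit_order), " blocks)\n",
      sep = "")
  invisible(x)
}
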