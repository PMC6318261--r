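#' Connectivity matrix container
#'
#' A nonnegative seeds x targets matrix of streamline visitation counts (or
#' length-weighted counts, or a group average), tied to the seed and target
#' spaces it is defined on.
#'
#' @param values Nonnegative numeric matrix, `n_seeds x n_targets`. Dense
#'   matrices and `Matrix` sparse matrices are both accepted; matrices with
#'   density below 25% are stored sparse.
#' @param seed_space A [seed_space()].
#' @param target_space A [target_space()].
#' @param weighting One of `"raw-counts"`, `"length-weighted"`, `"averaged"`.
#' @param n_subjects_averaged Number of subjects averaged into `values`
#'   (1 for a single-subject matrix).
#' @return An object of class `tractica_connmat`.
#' @export
connectivity_matrix <- function(values, seed_space, target_space,
                                weighting = c("raw-counts", "length-weighted",
                                              "averaged"),
                                n_subjects_averaged = 1L) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(seed_space, "tractica_seed_space"),
            inherits(target_space, "tractica_target_space"))
  if (nrow(values) != seed_space$n_seeds ||
      ncol(values) != target_space$n_targets)
    stop("values must be ", seed_space$n_seeds, " x ", target_space$n_targets,
         ", got ", nrow(values), " x ", ncol(values))
  vr <- range_finite(values)
  if (vr[1L] < 0) stop("connectivity values must be nonnegative")
  n_subjects_averaged <- as.integer(n_subjects_averaged)
  if (n_subjects_averaged < 1L) stop("n_subjects_averaged must be >= 1")
  values <- store_matrix(values)
  structure(list(values = values, seed_space = seed_space,
                 target_space = target_space, weighting = weighting,
                 n_subjects_averaged = n_subjects_averaged),
            class = "tractica_connmat")
}

# range check that also rejects NA/NaN/Inf
range_finite <- function(values) {
  x <- if (inherits(values, "sparseMatrix")) values@x else as.numeric(values)
  if (length(x) && !all(is.finite(x))) stop("values must all be finite")
  if (!length(x)) return(c(0, 0))
  range(x)
}

# keep sparse when density < 25%, dense otherwise
store_matrix <- function(values) {
  if (inherits(values, "sparseMatrix")) {
    dens <- Matrix::nnzero(values) / prod(dim(values))
    if (dens >= 0.25) return(as.matrix(values))
    return(methods::as(values, "CsparseMatrix"))
  }
  values <- as.matrix(values)
  dens <- sum(values != 0) / length(values)
  if (dens < 0.25)
    return(methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                   "generalMatrix"), "CsparseMatrix"))
  values
}

# dense numeric view used by numeric routines
dense_values <- function(x) {
  v <- if (inherits(x, "tractica_connmat")) x$values else x
  if (inherits(v, "Matrix")) as.matrix(v) else v
}

#' @export
print.tractica_connmat <- function(x, ...) {
  cat("<tractica_connmat> ", nrow(x$values), " seeds x ", ncol(x$values),
      " targets, weighting=", x$weighting,
      ", n_subjects_averaged=", x$n_subjects_averaged, "\n", sep = "")
  invisible(x)
}

#' Read a probtrackx2 "matrix2"-style sparse triplet file
#'
#' Parses whitespace-separated `i j value` rows with 1-based seed/target
#' indices (the `fdt_matrix2.dot` dialect) into a connectivity matrix.
#' Unlisted entries are zero; duplicated `(i, j)` entries are summed, since
#' matrix2 outputs may be written in chunks.
#'
#' @param triplet_path Path to the triplet text file.
#' @param seed_space,target_space Spaces declaring the expected dimensions.
#' @return A [connectivity_matrix()] with weighting `"raw-counts"`.
#' @export
read_probtrackx_matrix <- function(triplet_path, seed_space, target_space) {
  stopifnot(inherits(seed_space, "tractica_seed_space"),
            inherits(target_space, "tractica_target_space"))
  lines <- readLines(triplet_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- seed_space$n_seeds
  m <- target_space$n_targets
  if (length(lines) == 0L) {
    return(connectivity_matrix(matrix(0, n, m), seed_space, target_space,
                               weighting = "raw-counts"))
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(fields) != 3L)
  if (length(bad))
    stop("malformed triplet row ", bad[1L], ": expected 'i j value', got '",
         lines[bad[1L]], "'")
  rec <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = 3L, byrow = TRUE)
  bad <- which(!is.finite(rec[, 1L]) | !is.finite(rec[, 2L]) |
                 !is.finite(rec[, 3L]) |
                 rec[, 1L] != round(rec[, 1L]) | rec[, 2L] != round(rec[, 2L]))
  if (length(bad))
    stop("malformed triplet row ", bad[1L], ": '", lines[bad[1L]], "'")
  oob <- which(rec[, 1L] < 1 | rec[, 1L] > n | rec[, 2L] < 1 | rec[, 2L] > m)
  if (length(oob))
    stop("row ", oob[1L], ": index (", rec[oob[1L], 1L], ", ",
         rec[oob[1L], 2L], ") outside declared ", n, " x ", m, " matrix")
  neg <- which(rec[, 3L] < 0)
  if (length(neg))
    stop("row ", neg[1L], ": negative count ", rec[neg[1L], 3L])
  # sparseMatrix sums duplicated (i, j) pairs on CsparseMatrix conversion
  values <- Matrix::sparseMatrix(i = as.integer(rec[, 1L]),
                                 j = as.integer(rec[, 2L]),
                                 x = rec[, 3L], dims = c(n, m))
  connectivity_matrix(values, seed_space, target_space,
                      weighting = "raw-counts")
}
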