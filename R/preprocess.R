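#' Distance-weight a count matrix
#'
#' Multiplies each visitation count by the expected length (mm) of the tracts
#' reaching that entry, compensating for the distance bias of probabilistic
#' tractography: longer tracts accumulate more orientation uncertainty and
#' therefore lower visitation counts. Entries with zero count stay zero
#' whatever their length.
#'
#' @param matrix A raw-counts [connectivity_matrix()].
#' @param lengths Per-entry expected tract length in mm, either a full
#'   `n_seeds x n_targets` matrix or a per-target vector (broadcast across
#'   seeds, with a message, for pipelines that only store a target profile).
#' @return A [connectivity_matrix()] with weighting `"length-weighted"`.
#' @export
distance_weight <- function(matrix, lengths) {
  stopifnot(inherits(matrix, "tractica_connmat"))
  v <- dense_values(matrix)
  if (is.null(dim(lengths))) {
    if (length(lengths) != ncol(v))
      stop("per-target length vector has length ", length(lengths),
           ", expected ", ncol(v))
    message("broadcasting per-target length vector across seeds")
    lengths <- base::matrix(lengths, nrow(v), ncol(v), byrow = TRUE)
  }
  lengths <- as.matrix(lengths)
  if (!all(dim(lengths) == dim(v)))
    stop("lengths shape ", nrow(lengths), " x ", ncol(lengths),
         " does not match matrix ", nrow(v), " x ", ncol(v))
  bad <- which(v > 0 & !(lengths > 0), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("nonpositive length at nonzero count, entry (", bad[1L, 1L], ", ",
         bad[1L, 2L], ")")
  out <- v * lengths
  out[v == 0] <- 0
  connectivity_matrix(out, matrix$seed_space, matrix$target_space,
                      weighting = "length-weighted",
                      n_subjects_averaged = matrix$n_subjects_averaged)
}

#' Average connectivity matrices across subjects
#'
#' Element-wise arithmetic mean of per-subject matrices sharing the same
#' spaces and weighting; the result is the single representative matrix the
#' group decomposition consumes. Raw and length-weighted matrices must not be
#' mixed.
#'
#' @param matrices List of [connectivity_matrix()] objects (length >= 1).
#' @return A [connectivity_matrix()] with weighting `"averaged"` and
#'   `n_subjects_averaged` equal to the list length.
#' @export
group_average <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 1L)
    stop("need a non-empty list of connectivity matrices")
  stopifnot(all(vapply(matrices, inherits, TRUE, "tractica_connmat")))
  tags <- vapply(matrices, function(m) m$weighting, "")
  if (length(unique(tags)) > 1L)
    stop("mixed weighting tags: ", paste(unique(tags), collapse = ", "),
         " (raw and length-weighted matrices must not be averaged together)")
  dims <- vapply(matrices, function(m) dim(m$values), integer(2L))
  if (any(dims != dims[, 1L]))
    stop("matrices must share the same spaces")
  acc <- dense_values(matrices[[1L]])
  if (length(matrices) > 1L) {
    for (m in matrices[-1L]) acc <- acc + dense_values(m)
  }
  connectivity_matrix(acc / length(matrices),
                      matrices[[1L]]$seed_space,
                      matrices[[1L]]$target_space,
                      weighting = "averaged",
                      n_subjects_averaged = length(matrices))
}
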