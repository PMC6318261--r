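#' Dual regression of group components onto a single subject
#'
#' Projects a group decomposition onto an unseen subject's connectivity
#' matrix in two independent regressions: the group grey-matter maps form
#' the design over seeds and yield subject-specific white-matter maps
#' (stage 1), and the group white-matter maps form the design over targets
#' and yield subject-specific grey-matter maps (stage 2). Both stages are
#' joint multiple regressions over all K maps with variance-normalised
#' designs; the count matrix is not demeaned by default because zero counts
#' are meaningful.
#'
#' @param group A complete `tractica_components` (gm and wm maps).
#' @param subject_matrix The subject's [connectivity_matrix()] on the same
#'   spaces.
#' @param demean If `TRUE`, columns of the data are demeaned before each
#'   regression (fMRI-style); default `FALSE`.
#' @return A `tractica_components` holding the subject's gm and wm maps
#'   (unordered: component k corresponds to group component k).
#' @export
dual_regress <- function(group, subject_matrix, demean = FALSE) {
  stopifnot(inherits(group, "tractica_components"))
  if (is.null(group$wm_maps)) stop("group components incomplete: no wm_maps")
  M <- dense_values(subject_matrix)
  if (ncol(group$gm_maps) != nrow(M) || ncol(group$wm_maps) != ncol(M))
    stop("subject matrix dimensions do not match the group decomposition")
  sub_wm <- ls_stage(group$gm_maps, M, demean)        # K x n_targets
  sub_gm <- ls_stage(group$wm_maps, t(M), demean)     # K x n_seeds
  structure(list(
    K = group$K, gm_maps = sub_gm, wm_maps = sub_wm,
    ordering = "group-matched", sign_convention = group$sign_convention,
    provenance = list(stage = "dual-regression", demean = demean)
  ), class = "tractica_components")
}

# regress the K design maps (rows of D, over the rows of M) onto M
ls_stage <- function(D, M, demean) {
  sds <- apply(D, 1L, stats::sd)
  if (any(sds == 0)) stop("zero-variance design map")
  D <- D / sds
  if (demean) M <- sweep(M, 2L, colMeans(M))
  gram <- tcrossprod(D)
  if (kappa(gram, exact = TRUE) > 1e8)
    stop("collinear design: condition number exceeds 1e8")
  solve(gram, D %*% M)
}

#' Scalar subject weights per component
#'
#' Summarises each subject-component pair with two scalars: the dot product
#' of the group grey-matter map with the subject grey-matter map (node
#' strength) and of the group white-matter map with the subject white-matter
#' map (edge strength). By default the group (design) maps are scaled to
#' unit norm and the subject maps enter raw, so a subject identical to the
#' group (whose maps are then unit-norm themselves) scores 1 while
#' subject-specific scale is preserved.
#'
#' @param group,subject `tractica_components` objects of matching shapes.
#' @param normalize `"group"` (default: unit-norm group maps, raw subject
#'   maps), `"both"` (cosine similarity) or `"none"` (raw dot products).
#' @return A tibble with `component`, `gm_weight`, `wm_weight`.
#' @export
component_weights <- function(group, subject,
                              normalize = c("group", "both", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(group, "tractica_components"),
            inherits(subject, "tractica_components"),
            group$K == subject$K)
  w_for <- function(Gm, Sm) {
    vapply(seq_len(nrow(Gm)), function(k) {
      g <- Gm[k, ]; s <- Sm[k, ]
      if (normalize %in% c("group", "both")) g <- g / l2norm(g)
      if (normalize == "both") s <- s / l2norm(s)
      sum(g * s)
    }, numeric(1L))
  }
  tibble::tibble(
    component = seq_len(group$K),
    gm_weight = w_for(group$gm_maps, subject$gm_maps),
    wm_weight = w_for(group$wm_maps, subject$wm_maps)
  )
}

l2norm <- function(x) {
  n <- sqrt(sum(x^2))
  if (n == 0) 1 else n
}

#' Dual-regress a cohort and collect subject weights
#'
#' Convenience wrapper running [dual_regress()] and [component_weights()]
#' over a list of subject matrices.
#'
#' @param group A complete `tractica_components`.
#' @param subject_matrices Named or unnamed list of subject
#'   [connectivity_matrix()] objects.
#' @param ... Passed to [component_weights()].
#' @return A tibble with `subject`, `component`, `gm_weight`, `wm_weight`,
#'   of class `tractica_weights`.
#' @export
cohort_weights <- function(group, subject_matrices, ...) {
  ids <- names(subject_matrices)
  if (is.null(ids)) ids <- as.character(seq_along(subject_matrices))
  rows <- lapply(seq_along(subject_matrices), function(s) {
    sub <- dual_regress(group, subject_matrices[[s]])
    w <- component_weights(group, sub, ...)
    tibble::tibble(subject = ids[s], component = w$component,
                   gm_weight = w$gm_weight, wm_weight = w$wm_weight)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tractica_weights", class(out))
  out
}
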