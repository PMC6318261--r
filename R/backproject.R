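#' Back-project grey-matter maps onto the full connectivity matrix
#'
#' Recovers each component's white-matter pathway map by linear regression:
#' the K grey-matter maps jointly form the design matrix and every target
#' column of the full matrix is regressed on them at once (one multiple
#' regression per target, not K marginal regressions). For orthonormal maps
#' this reduces to the projection `gm_maps %*% matrix`.
#'
#' @param components A `tractica_components` object (or a bare `K x n_seeds`
#'   matrix of maps).
#' @param matrix The full [connectivity_matrix()] the maps were derived from.
#' @param normalize `"variance"` (default) scales each map to unit variance
#'   before the regression; `"none"` uses the maps as given.
#' @return If `components` is a component set, the same object with `wm_maps`
#'   filled in; otherwise the bare `K x n_targets` coefficient matrix.
#' @export
backproject <- function(components, matrix, normalize = c("variance", "none")) {
  normalize <- match.arg(normalize)
  is_set <- inherits(components, "tractica_components")
  G <- if (is_set) components$gm_maps else as.matrix(components)
  M <- if (inherits(matrix, "tractica_connmat")) dense_values(matrix) else
    as.matrix(matrix)
  if (ncol(G) != nrow(M))
    stop("gm_maps cover ", ncol(G), " seeds but the matrix has ", nrow(M))
  if (normalize == "variance") {
    sds <- apply(G, 1L, stats::sd)
    if (any(sds == 0)) stop("zero-variance map cannot be normalized")
    G <- G / sds
  }
  gram <- tcrossprod(G)
  if (kappa(gram, exact = TRUE) > 1e8)
    stop("collinear grey-matter maps: design condition number exceeds 1e8")
  wm <- solve(gram, G %*% M)
  if (!is_set) return(wm)
  components$wm_maps <- wm
  components$provenance$backproject_normalize <- normalize
  components
}

#' Group ICA of a tractography connectivity matrix
#'
#' The full decomposition pipeline: [migp_reduce()] to compress the target
#' dimension, [fit_ica()] for seed-domain independent components, and
#' [backproject()] for the paired white-matter maps. With
#' `domain = "tract"` the roles of seeds and targets are swapped, imposing
#' independence on the tractography domain instead (the variant appropriate
#' when white-matter pathways, not grey-matter parcels, should be
#' non-overlapping).
#'
#' @param matrix The (usually group-averaged) [connectivity_matrix()].
#' @param K Number of components; must be chosen a priori.
#' @param d Retained PCA dimension (default: 4000 capped at the matrix
#'   dimensions).
#' @param b MIGP block size (default: 10,000 capped at `n_targets`, floored
#'   at `d`).
#' @param domain `"seed"` (default) or `"tract"`.
#' @param nonlinearity,tol,max_iter,n_restarts FastICA options, see
#'   [fit_ica()].
#' @param rng_seed Master seed; MIGP and ICA stage seeds are derived from it.
#' @return A complete `tractica_components` object (gm and wm maps), with
#'   provenance recording every parameter.
#' @export
decompose_group <- function(matrix, K, d = NULL, b = NULL,
                            domain = c("seed", "tract"),
                            nonlinearity = "logcosh", tol = 1e-6,
                            max_iter = 1000L, n_restarts = 3L,
                            rng_seed = 1L) {
  domain <- match.arg(domain)
  stopifnot(inherits(matrix, "tractica_connmat"))
  M <- dense_values(matrix)
  if (domain == "tract") M <- t(M)
  n <- nrow(M); m <- ncol(M)
  if (is.null(d)) d <- min(4000L, n, m)
  if (is.null(b)) b <- max(min(10000L, m), d)
  reduced <- migp_reduce_raw(M, d, b, rng_seed = rng_seed)
  comps <- fit_ica(reduced, K, nonlinearity = nonlinearity, tol = tol,
                   max_iter = max_iter, n_restarts = n_restarts,
                   rng_seed = rng_seed + 1000L)
  other <- backproject(comps$gm_maps, M, normalize = "variance")
  if (domain == "seed") {
    comps$wm_maps <- other
  } else {
    # independence was imposed over targets; swap back so gm_maps are over
    # seeds and wm_maps over targets
    comps <- structure(list(
      K = comps$K, gm_maps = other, wm_maps = comps$gm_maps,
      ordering = comps$ordering, sign_convention = comps$sign_convention,
      provenance = comps$provenance
    ), class = "tractica_components")
  }
  comps$provenance <- c(comps$provenance,
                        list(d_used = d, b_used = b, domain = domain,
                             master_seed = rng_seed,
                             weighting = matrix$weighting,
                             n_subjects_averaged = matrix$n_subjects_averaged))
  comps
}

# migp on a bare matrix (internal: decompose_group may transpose, so the
# connmat wrapper types do not apply)
migp_reduce_raw <- function(X, d, b, rng_seed) {
  n <- nrow(X); m <- ncol(X)
  if (n == 0L || m == 0L) stop("empty matrix")
  if (d > min(n, m))
    stop("d = ", d, " exceeds min(dim) = ", min(n, m))
  if (min(b, m) < d) stop("block size b = ", b, " smaller than d = ", d)
  blocks <- withr::with_seed(rng_seed, {
    perm <- sample.int(m)
    split(perm, ceiling(seq_along(perm) / b))
  })
  W <- NULL
  for (blk in blocks) {
    C <- cbind(W, X[, blk, drop = FALSE])
    k <- min(d, ncol(C))
    sv <- svd(C, nu = k, nv = 0L)
    W <- sv$u %*% diag(sv$d[seq_len(k)], k)
  }
  structure(list(values = W, d = d, b = b, visit_order = unname(blocks),
                 rng_seed = rng_seed), class = "tractica_reduced")
}
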