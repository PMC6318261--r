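#' Seed-domain FastICA on a reduced matrix
#'
#' Extracts `K` spatial source maps over seeds from a MIGP-reduced matrix,
#' maximising non-Gaussianity with symmetric (parallel) FastICA. Independence
#' is enforced in the seed domain: the grey-matter maps are mutually
#' statistically independent while their white-matter counterparts (obtained
#' later by [backproject()]) are free to overlap. Rows of the result are
#' sign-fixed to positive skewness, scaled to unit variance, and ordered by
#' variance explained in the reduced matrix (descending). Several random
#' restarts are run and the solution with the best negentropy objective is
#' kept.
#'
#' @param reduced A [migp_reduce()] result (or any object with an
#'   `n_seeds x d` `values` field).
#' @param K Number of components (<= d).
#' @param nonlinearity FastICA contrast, `"logcosh"` (default) or `"exp"`.
#' @param tol Convergence tolerance on the update of the unmixing matrix.
#' @param max_iter Maximum FastICA iterations per restart.
#' @param n_restarts Random restarts; the best converged solution wins.
#' @param rng_seed Integer seed for initial unmixing matrices.
#' @param center If `TRUE`, remove each reduced dimension's mean over seeds
#'   before whitening (the fMRI convention). The default is `FALSE`:
#'   visitation counts have a meaningful zero, and on per-seed-normalised
#'   matrices demeaning removes exactly one rank of signal because the
#'   constant seed vector lies in the span of the scaled component maps.
#' @return A `tractica_components` object with `gm_maps` (`K x n_seeds`) and
#'   `wm_maps = NULL`.
#' @export
fit_ica <- function(reduced, K, nonlinearity = c("logcosh", "exp"),
                    tol = 1e-6, max_iter = 1000L, n_restarts = 3L,
                    rng_seed = 1L, center = FALSE) {
  nonlinearity <- match.arg(nonlinearity)
  X <- reduced$values           # n_seeds x d
  n <- nrow(X); d <- ncol(X)
  if (K > d) stop("K = ", K, " exceeds reduced dimension d = ", d)

  # whiten in the seed domain: rows of Z are K uncorrelated signals over the
  # n seeds with unit second moment
  Xt <- t(X)
  if (center) Xt <- Xt - rowMeans(Xt)
  sv <- svd(Xt, nu = K, nv = K)
  if (sv$d[K] <= 1e-12 * sv$d[1L])
    stop("reduced matrix has numerical rank < K = ", K)
  Z <- sqrt(n) * t(sv$v[, seq_len(K), drop = FALSE])

  const_G <- switch(nonlinearity, logcosh = 0.3745672, exp = -1 / sqrt(2))
  best <- NULL
  diagnostics <- list()
  for (r in seq_len(n_restarts)) {
    W0 <- withr::with_seed(rng_seed + r - 1L,
                           matrix(stats::rnorm(K * K), K, K))
    fit <- fastica_core(Z, W0, nonlinearity, tol, max_iter)
    diagnostics[[r]] <- list(converged = fit$converged, iter = fit$iter,
                             delta = fit$delta)
    if (!fit$converged) next
    S <- fit$W %*% Z
    obj <- sum((rowMeans(contrast_G(S, nonlinearity)) - const_G)^2)
    if (is.null(best) || obj > best$obj)
      best <- list(S = S, obj = obj, iter = fit$iter)
  }
  if (is.null(best)) {
    info <- paste(vapply(diagnostics, function(x)
      sprintf("iter=%d delta=%.2e", x$iter, x$delta), ""), collapse = "; ")
    stop("FastICA failed to converge in all ", n_restarts, " restarts (",
         info, ")")
  }

  S <- fix_components(best$S)
  ord <- order(variance_explained(S, X), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  structure(list(
    K = K, gm_maps = S, wm_maps = NULL,
    ordering = "variance-explained-desc",
    sign_convention = "positive-skewness",
    provenance = list(d = d, K = K, nonlinearity = nonlinearity, tol = tol,
                      max_iter = max_iter, n_restarts = n_restarts,
                      rng_seed = rng_seed, objective = best$obj,
                      iterations = best$iter)
  ), class = "tractica_components")
}

contrast_G <- function(S, nonlinearity) {
  switch(nonlinearity,
         logcosh = log(cosh(S)),
         exp = -exp(-S^2 / 2))
}

# symmetric FastICA on whitened K x n data
fastica_core <- function(Z, W0, nonlinearity, tol, max_iter) {
  n <- ncol(Z)
  W <- sym_decorrelate(W0)
  delta <- Inf
  for (it in seq_len(max_iter)) {
    S <- W %*% Z
    if (nonlinearity == "logcosh") {
      g <- tanh(S)
      gp_mean <- rowMeans(1 - g^2)
    } else {
      e <- exp(-S^2 / 2)
      g <- S * e
      gp_mean <- rowMeans((1 - S^2) * e)
    }
    W1 <- g %*% t(Z) / n - gp_mean * W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol)
      return(list(W = W, converged = TRUE, iter = it, delta = delta))
  }
  list(W = W, converged = FALSE, iter = max_iter, delta = delta)
}

# W <- (W W^T)^(-1/2) W
sym_decorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  e$vectors %*% (t(e$vectors) / sqrt(pmax(e$values, 1e-300)))  %*% W
}

# sign by positive skewness (ties: positive max-magnitude element), then unit
# variance per row
fix_components <- function(S) {
  for (k in seq_len(nrow(S))) {
    s <- S[k, ]
    s_c <- s - mean(s)
    sk <- mean(s_c^3)
    flip <- if (sk != 0) sk < 0 else s[which.max(abs(s))] < 0
    if (flip) s <- -s
    S[k, ] <- s / stats::sd(s)
  }
  S
}

# variance of the reduced matrix explained by each map alone, via the joint
# least-squares fit of all K maps
variance_explained <- function(S, X) {
  B <- solve(tcrossprod(S), S %*% X)   # K x d coefficients
  rowSums(B^2)
}

#' @export
print.tractica_components <- function(x, ...) {
  cat("<tractica_components> K=", x$K, ", gm_maps ", nrow(x$gm_maps), " x ",
      ncol(x$gm_maps), ", wm_maps ",
      if (is.null(x$wm_maps)) "absent" else
        paste0(nrow(x$wm_maps), " x ", ncol(x$wm_maps)),
      "\n", sep = "")
  invisible(x)
}
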