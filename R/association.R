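#' Spearman screening of subject weights against covariates
#'
#' Rank-correlates every (weight kind, component) pair of subject weights
#' with every numeric covariate: Spearman's rho with average ranks for ties,
#' two-sided p-values from the exact permutation distribution for n <= 9
#' complete pairs and the large-sample approximation otherwise. Missing
#' covariate values are handled pairwise-complete; covariates that are
#' constant, or leave fewer than 4 complete pairs, are excluded with a
#' logged reason.
#'
#' @param weights A [cohort_weights()] tibble (columns `subject`,
#'   `component`, `gm_weight`, `wm_weight`).
#' @param covariates Data frame with a `subject` column and numeric
#'   covariate columns.
#' @return A tibble of class `tractica_assoc` with `weight_kind`,
#'   `component`, `covariate`, `rho`, `p`, plus an `excluded` attribute
#'   recording skipped tests.
#' @export
spearman_screen <- function(weights, covariates) {
  stopifnot(is.data.frame(weights), is.data.frame(covariates),
            "subject" %in% names(covariates))
  cov_names <- setdiff(names(covariates), "subject")
  cov_names <- cov_names[vapply(covariates[cov_names], is.numeric, TRUE)]
  if (!length(cov_names)) stop("no numeric covariate columns")
  comps <- sort(unique(weights$component))
  rows <- list(); excluded <- list()
  for (kind in c("gm", "wm")) {
    wcol <- paste0(kind, "_weight")
    for (k in comps) {
      wk <- weights[weights$component == k, c("subject", wcol)]
      for (cv in cov_names) {
        m <- merge(wk, covariates[, c("subject", cv)], by = "subject")
        ok <- stats::complete.cases(m[[wcol]], m[[cv]])
        n <- sum(ok)
        if (n < 4L) {
          excluded[[length(excluded) + 1L]] <-
            tibble::tibble(weight_kind = kind, component = k, covariate = cv,
                           reason = paste0("only ", n, " complete pairs"))
          next
        }
        x <- m[[wcol]][ok]; y <- m[[cv]][ok]
        if (stats::sd(y) == 0 || stats::sd(x) == 0) {
          excluded[[length(excluded) + 1L]] <-
            tibble::tibble(weight_kind = kind, component = k, covariate = cv,
                           reason = "constant variable")
          next
        }
        ct <- suppressWarnings(
          stats::cor.test(x, y, method = "spearman", exact = n <= 9L))
        rows[[length(rows) + 1L]] <-
          tibble::tibble(weight_kind = kind, component = k, covariate = cv,
                         rho = unname(ct$estimate), p = ct$p.value, n = n)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("all tests excluded")
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
                           else NULL
  class(out) <- c("tractica_assoc", class(out))
  out
}

#' False-discovery-rate correction
#'
#' Converts p-values to q-values either by the Storey approach (the null
#' proportion pi0 estimated by the smoother over a lambda grid, as in the
#' q-value literature) or by Benjamini-Hochberg step-up. Significance is
#' flagged at `q < q_cut`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param method `"storey"` (default) or `"bh"`.
#' @param q_cut Significance cut on the q-values (default 0.05).
#' @return A tibble with `p`, `q`, `significant`, in the input order;
#'   `pi0` is attached as an attribute for the Storey method.
#' @export
fdr_correct <- function(p_values, method = c("storey", "bh"), q_cut = 0.05) {
  method <- match.arg(method)
  p <- as.numeric(p_values)
  if (!length(p)) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  if (method == "bh") {
    q <- stats::p.adjust(p, method = "BH")
    pi0 <- NA_real_
  } else {
    pi0 <- storey_pi0(p)
    m <- length(p)
    rk <- rank(p, ties.method = "max")
    ord <- order(p, decreasing = TRUE)
    q <- numeric(m)
    running <- Inf
    for (i in ord) {
      running <- min(running, pi0 * p[i] * m / rk[i])
      q[i] <- running
    }
    q <- pmin(q, 1)
  }
  out <- tibble::tibble(p = p, q = q, significant = q < q_cut)
  attr(out, "pi0") <- pi0
  attr(out, "method") <- method
  out
}

# Storey pi0: natural cubic smoother of pi0(lambda) over a lambda grid,
# evaluated at the largest lambda
storey_pi0 <- function(p) {
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1L))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, 1e-8), 1)
}

#' Add FDR q-values to an association table
#'
#' Applies [fdr_correct()] across all rows of a [spearman_screen()] result
#' (Storey by default, with BH columns alongside for audit) and flags
#' significance at `q < q_cut`.
#'
#' @param table A `tractica_assoc` tibble.
#' @param q_cut Significance threshold (default 0.05).
#' @return The table with `q`, `significant` (Storey) and `q_bh`,
#'   `significant_bh` columns appended.
#' @export
add_fdr <- function(table, q_cut = 0.05) {
  st <- fdr_correct(table$p, method = "storey", q_cut = q_cut)
  bh <- fdr_correct(table$p, method = "bh", q_cut = q_cut)
  table$q <- st$q
  table$significant <- st$significant
  table$q_bh <- bh$q
  table$significant_bh <- bh$significant
  attr(table, "pi0") <- attr(st, "pi0")
  table
}

#' Spatial comparison of structural components with functional networks
#'
#' Correlates every structural grey-matter component map with every
#' functional network map over the non-excluded seeds (Pearson). Because the
#' structural components have minimal co-linearity, the squared correlations
#' act as fractions of spatial variance explained, summed per functional
#' network without capping at 1. A structure-function pair is called
#' significant when a structural component explains more than
#' `r2_threshold` (default 5%) of a functional map's variance, i.e.
#' `|r| > sqrt(r2_threshold)` (0.2236 for the default, printed as 0.22).
#'
#' @param components `tractica_components` (or `K x n_seeds` matrix).
#' @param rsn_maps `R x n_seeds` matrix of functional network spatial maps
#'   on the same seed space (resample upstream if needed).
#' @param seed_space Optional seed space supplying the exclusion mask.
#' @param r2_threshold Variance fraction for significance (default 0.05).
#' @param top_m Strongest pairs reported per functional network (default 2).
#' @return An object of class `tractica_structfunc`: `correlations`
#'   (`K x R`), `variance_explained` (tibble per network),
#'   `significant_pairs`, `top_pairs`, `r_cut`, and `flagged` (zero-variance
#'   maps skipped).
#' @export
structure_function <- function(components, rsn_maps, seed_space = NULL,
                               r2_threshold = 0.05, top_m = 2L) {
  G <- component_maps(components, "gm")
  Rm <- as.matrix(rsn_maps)
  if (ncol(G) != ncol(Rm))
    stop("rsn_maps must live on the same seed space (", ncol(G), " seeds)")
  keep <- if (!is.null(seed_space)) !seed_space$exclusion else
    rep(TRUE, ncol(G))
  Gk <- G[, keep, drop = FALSE]
  Rk <- Rm[, keep, drop = FALSE]
  sdG <- apply(Gk, 1L, stats::sd)
  sdR <- apply(Rk, 1L, stats::sd)
  flagged <- list(structural = which(sdG == 0), functional = which(sdR == 0))
  C <- matrix(NA_real_, nrow(G), nrow(Rm))
  okG <- sdG > 0; okR <- sdR > 0
  if (any(okG) && any(okR))
    C[okG, okR] <- stats::cor(t(Gk[okG, , drop = FALSE]),
                              t(Rk[okR, , drop = FALSE]))
  r_cut <- sqrt(r2_threshold)
  ve <- tibble::tibble(
    network = seq_len(nrow(Rm)),
    variance_explained = vapply(seq_len(nrow(Rm)), function(f)
      sum(C[, f]^2, na.rm = TRUE), numeric(1L))
  )
  idx <- which(abs(C) > r_cut, arr.ind = TRUE)
  sig <- tibble::tibble(component = idx[, 1L], network = idx[, 2L],
                        r = C[idx], r_squared = C[idx]^2)
  sig <- sig[order(sig$network, -abs(sig$r)), ]
  top <- do.call(rbind, lapply(seq_len(nrow(Rm)), function(f) {
    r <- C[, f]
    ord <- order(abs(r), decreasing = TRUE, na.last = TRUE)
    ord <- ord[seq_len(min(top_m, sum(!is.na(r))))]
    tibble::tibble(network = f, component = ord, r = r[ord])
  }))
  structure(list(correlations = C, variance_explained = ve,
                 significant_pairs = sig, top_pairs = top,
                 r_cut = r_cut, r2_threshold = r2_threshold,
                 flagged = flagged),
            class = "tractica_structfunc")
}

#' @export
print.tractica_structfunc <- function(x, ...) {
  cat("<tractica_structfunc> ", nrow(x$correlations), " components x ",
      ncol(x$correlations), " networks; ", nrow(x$significant_pairs),
      " pairs with |r| > ", round(x$r_cut, 2), "\n", sep = "")
  invisible(x)
}
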