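#' Winner-take-all hard parcellation
#'
#' Labels every seed by the component with the highest grey-matter weight at
#' that seed; exact ties go to the lowest component index, and excluded seeds
#' get label 0.
#'
#' @param components A `tractica_components` object (gm_maps present) or a
#'   bare `K x n_seeds` matrix.
#' @param seed_space The seed space (supplies the exclusion mask).
#' @return An object of class `tractica_parcellation` with integer `labels`
#'   in `0..K`.
#' @export
hard_parcellation <- function(components, seed_space) {
  G <- if (inherits(components, "tractica_components")) components$gm_maps
       else as.matrix(components)
  stopifnot(inherits(seed_space, "tractica_seed_space"),
            ncol(G) == seed_space$n_seeds)
  labels <- max.col(t(G), ties.method = "first")
  labels[seed_space$exclusion] <- 0L
  structure(list(labels = as.integer(labels), K = nrow(G),
                 source = "winner-take-all"),
            class = "tractica_parcellation")
}

#' @export
print.tractica_parcellation <- function(x, ...) {
  cat("<tractica_parcellation> ", length(x$labels), " seeds, K=", x$K,
      " labels (", sum(x$labels == 0L), " unassigned), source=", x$source,
      "\n", sep = "")
  invisible(x)
}

#' Match components between two decompositions
#'
#' For each component of `A`, finds the component of `B` whose grey-matter
#' map has the highest absolute Pearson correlation (best match with
#' replacement: the mapping may be non-injective). Zero-variance maps are
#' flagged and excluded.
#'
#' @param A,B `tractica_components` objects (or bare `K x n_seeds` matrices)
#'   on the same seed space.
#' @param use `"gm"` (default) or `"wm"` maps.
#' @return A tibble with columns `component`, `matched`, `r` (signed, at the
#'   matched pair), `abs_r`, and `flagged` for zero-variance rows.
#' @export
match_components <- function(A, B, use = c("gm", "wm")) {
  use <- match.arg(use)
  MA <- component_maps(A, use)
  MB <- component_maps(B, use)
  if (ncol(MA) != ncol(MB)) stop("component sets live on different spaces")
  sdA <- apply(MA, 1L, stats::sd)
  sdB <- apply(MB, 1L, stats::sd)
  okB <- sdB > 0
  out <- tibble::tibble(component = seq_len(nrow(MA)),
                        matched = NA_integer_, r = NA_real_,
                        abs_r = NA_real_, flagged = sdA == 0)
  if (!any(okB)) return(out)
  C <- suppressWarnings(stats::cor(t(MA), t(MB[okB, , drop = FALSE])))
  idxB <- which(okB)
  for (k in seq_len(nrow(MA))) {
    if (out$flagged[k]) next
    j <- which.max(abs(C[k, ]))
    out$matched[k] <- idxB[j]
    out$r[k] <- C[k, j]
    out$abs_r[k] <- abs(C[k, j])
  }
  out
}

component_maps <- function(x, use) {
  if (inherits(x, "tractica_components")) {
    m <- if (use == "gm") x$gm_maps else x$wm_maps
    if (is.null(m)) stop(use, "_maps absent")
    m
  } else as.matrix(x)
}

#' Dice overlap of two hard parcellations
#'
#' For matched label pairs `(k, k')`, `D = 2 |S_k intersect S_k'| /
#' (|S_k| + |S_k'|)` counted over non-excluded seeds. Labels need not be
#' spatially contiguous. With `matching = NULL` each label of `A` is matched
#' to the `B` label of maximum overlap (best match with replacement);
#' `method = "one-to-one"` instead assigns greedily by decreasing overlap
#' without reuse.
#'
#' @param A,B `tractica_parcellation` objects on the same seed space.
#' @param matching Optional two-column matrix / data frame of (label_a,
#'   label_b) pairs; computed from overlaps when `NULL`.
#' @param method `"best"` (default) or `"one-to-one"` for the automatic
#'   matching.
#' @return A list with `table` (tibble: label_a, label_b, dice) and `mean`;
#'   pairs empty on both sides are dropped from the mean with a warning.
#' @export
dice <- function(A, B, matching = NULL, method = c("best", "one-to-one")) {
  method <- match.arg(method)
  stopifnot(inherits(A, "tractica_parcellation"),
            inherits(B, "tractica_parcellation"),
            length(A$labels) == length(B$labels))
  la <- A$labels; lb <- B$labels
  supplied <- !is.null(matching)
  if (is.null(matching)) {
    ov <- overlap_table(la, lb, A$K, B$K)
    matching <- if (method == "best") {
      cbind(seq_len(A$K), max.col(ov, ties.method = "first"))
    } else greedy_assignment(ov)
  }
  matching <- as.matrix(matching)
  sizes_a <- tabulate(la[la > 0L], A$K)
  sizes_b <- tabulate(lb[lb > 0L], B$K)
  d <- numeric(nrow(matching))
  for (i in seq_len(nrow(matching))) {
    k <- matching[i, 1L]; kp <- matching[i, 2L]
    inter <- sum(la == k & lb == kp)
    denom <- sizes_a[k] + sizes_b[kp]
    d[i] <- if (denom == 0L) NA_real_ else 2 * inter / denom
  }
  if (anyNA(d))
    warning("label empty on both sides: ", sum(is.na(d)),
            " pair(s) excluded from the mean")
  list(table = tibble::tibble(label_a = matching[, 1L],
                              label_b = matching[, 2L], dice = d),
       mean = mean(d, na.rm = TRUE),
       method = if (supplied) "supplied" else method)
}

overlap_table <- function(la, lb, Ka, Kb) {
  ov <- matrix(0L, Ka, Kb)
  both <- la > 0L & lb > 0L
  if (any(both)) {
    t <- table(factor(la[both], levels = seq_len(Ka)),
               factor(lb[both], levels = seq_len(Kb)))
    ov <- ov + unclass(t)
  }
  ov
}

# greedy one-to-one assignment by decreasing overlap
greedy_assignment <- function(ov) {
  Ka <- nrow(ov); Kb <- ncol(ov)
  ord <- order(ov, decreasing = TRUE)
  used_a <- logical(Ka); used_b <- logical(Kb)
  pairs <- matrix(NA_integer_, 0L, 2L)
  for (idx in ord) {
    a <- (idx - 1L) %% Ka + 1L
    b <- (idx - 1L) %/% Ka + 1L
    if (used_a[a] || used_b[b]) next
    used_a[a] <- TRUE; used_b[b] <- TRUE
    pairs <- rbind(pairs, c(a, b))
    if (all(used_a) || all(used_b)) break
  }
  pairs[order(pairs[, 1L]), , drop = FALSE]
}

#' Contiguous random (Voronoi) parcellation
#'
#' Samples `K` seed-vertices uniformly among the non-excluded seeds and
#' labels every seed by its graph-geodesic nearest seed-vertex
#' (multi-source breadth-first search; ties go to the lower-index source).
#' Every parcel is connected in the adjacency graph and non-empty.
#'
#' @param seed_space A [seed_space()] whose non-excluded subgraph is
#'   connected.
#' @param K Number of parcels (<= number of non-excluded seeds).
#' @param rng_seed Integer seed.
#' @return A `tractica_parcellation` with source `"voronoi"`.
#' @export
random_voronoi_parcellation <- function(seed_space, K, rng_seed = 1L) {
  stopifnot(inherits(seed_space, "tractica_seed_space"))
  active <- which(!seed_space$exclusion)
  if (K > length(active)) stop("K exceeds the number of non-excluded seeds")
  comp <- graph_components(seed_space)
  ncomp <- length(unique(comp[comp > 0L]))
  if (ncomp > 1L)
    stop("adjacency graph disconnected on non-excluded seeds: ", ncomp,
         " components of sizes ",
         paste(sort(tabulate(comp[comp > 0L]), decreasing = TRUE),
               collapse = ", "))
  centers <- withr::with_seed(rng_seed, sample(active, K))
  voronoi_from_centers(seed_space, centers)
}

# multi-source BFS labelling; FIFO order gives nearest-source labels with
# ties resolved in favour of the earlier-queued (lower-index) source
voronoi_from_centers <- function(seed_space, centers) {
  adj <- adjacency_list(seed_space)
  n <- seed_space$n_seeds
  labels <- integer(n)
  queue <- integer(n)
  head <- 1L; tail <- 0L
  for (k in seq_along(centers)) {
    labels[centers[k]] <- k
    tail <- tail + 1L
    queue[tail] <- centers[k]
  }
  excl <- seed_space$exclusion
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (nb in adj[[v]]) {
      if (labels[nb] == 0L && !excl[nb]) {
        labels[nb] <- labels[v]
        tail <- tail + 1L
        queue[tail] <- nb
      }
    }
  }
  labels[excl] <- 0L
  structure(list(labels = labels, K = length(centers), source = "voronoi"),
            class = "tractica_parcellation")
}

#' Null distribution of mean Dice under contiguous random parcellations
#'
#' Draws `n_iter` independent pairs of random Voronoi parcellations at
#' dimensionality `K`, matches each pair by maximum label overlap, and
#' records the pair's mean Dice. The resulting distribution is the
#' chance-level reference against which split-half ICA parcellation
#' reproducibility is judged.
#'
#' @inheritParams random_voronoi_parcellation
#' @param n_iter Number of parcellation pairs (reference analyses use 1000).
#' @return Numeric vector of `n_iter` mean Dice values.
#' @export
voronoi_dice_null <- function(seed_space, K, n_iter = 1000L, rng_seed = 1L) {
  vapply(seq_len(n_iter), function(i) {
    p1 <- random_voronoi_parcellation(seed_space, K,
                                      rng_seed = rng_seed + 2L * i)
    p2 <- random_voronoi_parcellation(seed_space, K,
                                      rng_seed = rng_seed + 2L * i + 1L)
    dice(p1, p2)$mean
  }, numeric(1L))
}

#' Homologue (left/right) symmetry of component maps
#'
#' Correlates each grey-matter map with itself re-indexed through the seed
#' space's left/right homologue pairing, and classifies components as
#' bilateral (self-flip correlation at or above `bilateral_threshold`) or
#' lateralised to the hemisphere carrying the larger mass of suprathreshold
#' weight.
#'
#' @param components `tractica_components` (or `K x n_seeds` matrix).
#' @param seed_space Seed space with a homologue map covering (at least 95%
#'   of) both hemispheres.
#' @param bilateral_threshold Self-flip correlation at or above which a
#'   component counts as bilateral (default 0.9; configurable, and recorded
#'   in the output).
#' @param mass_quantile Quantile of the map above which weight counts as
#'   suprathreshold for the laterality mass comparison.
#' @return A tibble with `component`, `r`, `laterality`
#'   (`"bilateral"`, `"left"`, `"right"`).
#' @export
homologue_correlation <- function(components, seed_space,
                                  bilateral_threshold = 0.9,
                                  mass_quantile = 0.9) {
  G <- component_maps(components, "gm")
  stopifnot(inherits(seed_space, "tractica_seed_space"))
  h <- seed_space$homologue
  if (is.null(h)) stop("seed space has no homologue map")
  lat_seed <- seed_space$hemisphere %in% c("left", "right")
  unmapped <- mean(is.na(h[lat_seed]))
  if (unmapped > 0.05)
    stop("homologue map incomplete: ", round(100 * unmapped, 1),
         "% of hemispheric seeds unmapped (tolerance 5%)")
  dom <- which(!is.na(h) & !seed_space$exclusion)
  dom <- dom[!seed_space$exclusion[h[dom]]]
  res <- lapply(seq_len(nrow(G)), function(k) {
    m <- G[k, ]
    r <- suppressWarnings(stats::cor(m[dom], m[h[dom]]))
    if (is.na(r)) r <- 0
    if (r >= bilateral_threshold) {
      lat <- "bilateral"
    } else {
      thr <- stats::quantile(m, mass_quantile)
      supra <- m >= thr & !seed_space$exclusion
      mass_l <- sum(m[supra & seed_space$hemisphere == "left"])
      mass_r <- sum(m[supra & seed_space$hemisphere == "right"])
      lat <- if (mass_l >= mass_r) "left" else "right"
    }
    tibble::tibble(component = k, r = r, laterality = lat)
  })
  out <- do.call(rbind, res)
  attr(out, "bilateral_threshold") <- bilateral_threshold
  out
}
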