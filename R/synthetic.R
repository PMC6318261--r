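#' Toy mirrored seed/target spaces
#'
#' Builds a pair of small spaces for simulation and testing: two mirrored
#' grey-matter seed lattices (one per hemisphere) with 4-neighbour adjacency
#' and a complete left/right homologue map, plus a 3-D target voxel grid with
#' mm coordinates. Geometry is deterministic given the arguments.
#'
#' @param n_per_hemi Seeds per hemisphere (>= 4).
#' @param grid Target grid dimensions, 3 integers all >= 2.
#' @param voxel_size Target voxel size in mm.
#' @param rng_seed Accepted for interface symmetry with the other generators;
#'   construction is deterministic.
#' @return A list with elements `seed_space` and `target_space`.
#' @export
make_toy_spaces <- function(n_per_hemi, grid = c(5L, 5L, 5L), voxel_size = 3,
                            rng_seed = 1L) {
  if (n_per_hemi < 4L) stop("n_per_hemi must be >= 4")
  grid <- as.integer(grid)
  if (length(grid) != 3L || any(grid < 2L))
    stop("degenerate grid: all dimensions must be >= 2")

  # per-hemisphere lattice, row-major fill of a near-square grid
  ncol_l <- ceiling(sqrt(n_per_hemi))
  pos <- arrayInd(seq_len(n_per_hemi), c(ceiling(n_per_hemi / ncol_l), ncol_l))
  edges <- lattice_edges(pos)
  n <- 2L * n_per_hemi
  edges_both <- rbind(edges, edges + n_per_hemi)
  # midline bridge: homologous seeds of the first lattice column are joined,
  # keeping the full graph connected for contiguous random parcellations
  bridge <- which(pos[, 2L] == 1L)
  edges_both <- rbind(edges_both, cbind(bridge, bridge + n_per_hemi))

  extent <- grid * voxel_size
  dy <- extent[2L] / (max(pos[, 2L]) + 1)
  dz <- extent[3L] / (max(pos[, 1L]) + 1)
  y <- (pos[, 2L] - (max(pos[, 2L]) + 1) / 2) * dy
  z <- (pos[, 1L] - (max(pos[, 1L]) + 1) / 2) * dz
  xoff <- 0.3 * extent[1L]
  coords <- rbind(cbind(-xoff, y, z), cbind(xoff, y, z))

  ss <- seed_space(
    seed_ids = sprintf("%s%04d", rep(c("L", "R"), each = n_per_hemi),
                       rep(seq_len(n_per_hemi), 2L)),
    kind = "volume-voxel",
    hemisphere = rep(c("left", "right"), each = n_per_hemi),
    edges = edges_both,
    homologue = c(seq_len(n_per_hemi) + n_per_hemi, seq_len(n_per_hemi)),
    coordinates = coords,
    grid_shape = grid,
    affine = centered_affine(grid, voxel_size)
  )
  ts <- target_space(grid, centered_affine(grid, voxel_size))
  list(seed_space = ss, target_space = ts)
}

# voxel-to-mm affine placing the grid centre at the origin
centered_affine <- function(grid, voxel_size) {
  aff <- diag(4)
  diag(aff)[1:3] <- voxel_size
  aff[1:3, 4L] <- -voxel_size * (grid - 1) / 2
  aff
}

# 4-neighbour edges of lattice positions (row, col), 1-based seed indices
lattice_edges <- function(pos) {
  key <- paste(pos[, 1L], pos[, 2L])
  idx <- seq_len(nrow(pos))
  names(idx) <- key
  out <- list()
  for (i in idx) {
    right <- idx[paste(pos[i, 1L], pos[i, 2L] + 1L)]
    down <- idx[paste(pos[i, 1L] + 1L, pos[i, 2L])]
    if (!is.na(right)) out[[length(out) + 1L]] <- c(i, right)
    if (!is.na(down)) out[[length(out) + 1L]] <- c(i, down)
  }
  if (!length(out)) matrix(integer(), ncol = 2L) else do.call(rbind, out)
}

#' Synthetic ground truth for multi-subject connectivity matrices
#'
#' Plants `K_true` grey-matter component maps with sparse, dominantly
#' disjoint (but overlapping) supports, paired white-matter fingerprints
#' built from smooth spatial bumps over the target grid, log-normal
#' subject-specific component loadings, a distance-dependent count
#' attenuation, and a per-entry expected tract-length matrix.
#'
#' @param seed_space,target_space Spaces from [make_toy_spaces()] or real
#'   geometry.
#' @param K_true Number of planted components (<= n_seeds / 2).
#' @param sparsity Target support size of each component as a fraction of the
#'   non-excluded seeds; values above `1/K_true` create overlap between
#'   component supports.
#' @param n_subjects Number of subjects to draw loadings for.
#' @param loading_sd Standard deviation of log subject loadings; 0 gives
#'   every subject unit loadings.
#' @param count_scale Expected total streamline count per seed (default 5000).
#' @param distance_decay Exponential attenuation rate of counts with
#'   seed--target distance, per mm.
#' @param rng_seed Integer seed; identical inputs give identical output.
#' @return An object of class `tractica_ground_truth`.
#' @export
make_ground_truth <- function(seed_space, target_space, K_true,
                              sparsity = 0.15, n_subjects = 10L,
                              loading_sd = 0.5, count_scale = 5000,
                              distance_decay = 0.02, rng_seed = 1L) {
  stopifnot(inherits(seed_space, "tractica_seed_space"),
            inherits(target_space, "tractica_target_space"))
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  if (K_true > seed_space$n_seeds / 2)
    stop("K_true must be <= n_seeds / 2")
  if (is.null(seed_space$coordinates))
    stop("seed_space needs coordinates for the distance model")
  n <- seed_space$n_seeds
  m <- target_space$n_targets
  active <- which(!seed_space$exclusion)

  gt <- withr::with_seed(rng_seed, {
    # primary supports: a balanced random partition of active seeds, so every
    # non-excluded seed is covered by construction
    primary <- sample(rep_len(seq_len(K_true), length(active)))
    gm <- matrix(0, K_true, n)
    s_target <- ceiling(sparsity * length(active))
    for (k in seq_len(K_true)) {
      members <- active[primary == k]
      gm[k, members] <- stats::runif(length(members), 0.8, 1.2)
      extra <- s_target - length(members)
      if (extra > 0) {
        pool <- setdiff(active, members)
        sec <- sample(pool, min(extra, length(pool)))
        gm[k, sec] <- stats::runif(length(sec), 0.2, 0.5)
      }
    }
    # white-matter fingerprints: two gaussian bumps over target coordinates
    tc <- target_space$coordinates
    sigma <- 0.2 * max(apply(tc, 2L, function(v) diff(range(v))))
    wm <- matrix(0, K_true, m)
    for (k in seq_len(K_true)) {
      centers <- tc[sample(m, 2L), , drop = FALSE]
      w <- rowSums(vapply(seq_len(nrow(centers)), function(c_i) {
        d2 <- colSums((t(tc) - centers[c_i, ])^2)
        exp(-d2 / (2 * sigma^2))
      }, numeric(m)))
      w[w < 0.05 * max(w)] <- 0
      wm[k, ] <- w / sum(w)
    }
    lam <- matrix(exp(stats::rnorm(n_subjects * K_true, 0, loading_sd)),
                  n_subjects, K_true)
    list(gm = gm, wm = wm, lam = lam)
  })

  D <- seed_target_distance(seed_space, target_space)
  decay <- exp(-distance_decay * D)
  # population-baseline (unit-loading) row normaliser shared by all subjects:
  # an average subject's seeds emit count_scale expected streamlines each
  base_rate <- (t(gt$gm) %*% gt$wm) * decay
  row_tot <- rowSums(base_rate)
  row_scale <- ifelse(row_tot > 0, count_scale / row_tot, 0)

  structure(list(
    K_true = K_true, gm_true = gt$gm, wm_true = gt$wm,
    subject_loadings = gt$lam, count_scale = count_scale,
    distance_decay = distance_decay, decay = decay,
    row_scale = row_scale,
    length_matrix = D + 15,
    seed_space = seed_space, target_space = target_space,
    sparsity = sparsity, loading_sd = loading_sd, rng_seed = rng_seed
  ), class = "tractica_ground_truth")
}

seed_target_distance <- function(seed_space, target_space) {
  sc <- seed_space$coordinates
  tc <- target_space$coordinates
  d2 <- outer(rowSums(sc^2), rowSums(tc^2), "+") - 2 * sc %*% t(tc)
  sqrt(pmax(d2, 0))
}

#' @export
print.tractica_ground_truth <- function(x, ...) {
  cat("<tractica_ground_truth> K_true=", x$K_true, ", ",
      nrow(x$subject_loadings), " subjects, count_scale=", x$count_scale,
      ", distance_decay=", x$distance_decay, "\n", sep = "")
  invisible(x)
}

#' Noise-free expected count matrix for one subject
#'
#' The Poisson rate matrix of [sample_subject_matrix()]: the subject-loaded
#' sum of ground-truth outer products, attenuated with seed--target distance
#' and row-scaled by the shared population baseline so that an average
#' subject's seeds emit `count_scale` expected streamlines.
#'
#' @param gt A [make_ground_truth()] object.
#' @param subject_index Subject row in `gt$subject_loadings`.
#' @return Numeric `n_seeds x n_targets` rate matrix.
#' @export
subject_rate_matrix <- function(gt, subject_index) {
  stopifnot(inherits(gt, "tractica_ground_truth"))
  if (subject_index < 1L || subject_index > nrow(gt$subject_loadings))
    stop("subject_index out of range")
  lam <- gt$subject_loadings[subject_index, ]
  rate <- (t(gt$gm_true * lam) %*% gt$wm_true) * gt$decay
  rate * gt$row_scale
}

#' Planted component maps as expressed in the sampled matrices
#'
#' The grey-matter maps recoverable from the generated matrices are the
#' planted maps times the shared per-seed row scaling (the matrices are
#' row-normalised, so the observable seed weights are `row_scale * gm_true`);
#' the white-matter fingerprints are unaffected. Parameter-recovery tests
#' should compare decompositions against these observation-space maps.
#'
#' @param gt A [make_ground_truth()] object.
#' @return A list with `gm` (`K_true x n_seeds`) and `wm`
#'   (`K_true x n_targets`).
#' @export
ground_truth_maps <- function(gt) {
  stopifnot(inherits(gt, "tractica_ground_truth"))
  list(gm = t(t(gt$gm_true) * gt$row_scale), wm = gt$wm_true)
}

#' Draw one subject's streamline count matrix
#'
#' Entry `(i, j)` is Poisson with the rate given by
#' [subject_rate_matrix()]; streamline visitation counts are counts, so the
#' noise model is Poisson rather than Gaussian.
#'
#' @inheritParams subject_rate_matrix
#' @param rng_seed Integer seed; draws are reproducible.
#' @return A list with `matrix` (a raw-counts [connectivity_matrix()]) and
#'   `lengths` (the per-entry expected tract-length matrix in mm).
#' @export
sample_subject_matrix <- function(gt, subject_index, rng_seed = 1L) {
  rate <- subject_rate_matrix(gt, subject_index)
  counts <- withr::with_seed(rng_seed, {
    matrix(stats::rpois(length(rate), rate), nrow(rate), ncol(rate))
  })
  list(
    matrix = connectivity_matrix(counts, gt$seed_space, gt$target_space,
                                 weighting = "raw-counts"),
    lengths = gt$length_matrix
  )
}
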