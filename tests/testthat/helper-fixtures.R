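# Shared fixtures, all generated in code.

# minimal spaces of arbitrary size with a path-graph adjacency
tiny_spaces <- function(n_seeds = 2L, grid = c(2L, 2L, 2L)) {
  edges <- if (n_seeds > 1L) cbind(seq_len(n_seeds - 1L), 2:n_seeds) else NULL
  ss <- seed_space(seed_ids = sprintf("s%02d", seq_len(n_seeds)),
                   kind = "volume-voxel", hemisphere = "midline",
                   edges = edges)
  ts <- target_space(grid, diag(4))
  list(seed_space = ss, target_space = ts)
}

# wrap a bare matrix in a connectivity_matrix with matching tiny spaces
as_connmat <- function(values, weighting = "raw-counts") {
  values <- as.matrix(values)
  grids <- list(c(2L, 2L, 2L), c(2L, 2L, 3L), c(2L, 3L, 3L), c(3L, 3L, 3L),
                c(3L, 3L, 4L), c(3L, 4L, 4L), c(4L, 4L, 4L))
  grid <- NULL
  for (g in grids) if (prod(g) == ncol(values)) { grid <- g; break }
  if (is.null(grid)) grid <- c(1L, 1L, ncol(values))
  sp <- tiny_spaces(nrow(values), grid = pmax(grid, 2L))
  ts <- target_space(c(1L, 1L, ncol(values)) + c(1L, 1L, 0L), diag(4),
                     target_ids = seq_len(ncol(values)),
                     coordinates = cbind(0, 0, seq_len(ncol(values))))
  connectivity_matrix(values, sp$seed_space, ts, weighting = weighting)
}

write_triplets <- function(rows, path = tempfile(fileext = ".dot")) {
  writeLines(rows, path)
  path
}

# all permutations of 1..n (n small), as a list of integer vectors
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- combinat_perms(n - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(n)) {
    out[[length(out) + 1L]] <- append(p + (p >= n) * 0L, n, after = pos - 1L)
  }
  out
}

# small default simulation shared by several test files
default_sim <- function(n_per_hemi = 60L, K_true = 8L, n_subjects = 6L,
                        grid = c(6L, 6L, 6L), loading_sd = 0.5,
                        distance_decay = 0.02, rng_seed = 42L, ...) {
  spaces <- make_toy_spaces(n_per_hemi, grid = grid)
  gt <- make_ground_truth(spaces$seed_space, spaces$target_space,
                          K_true = K_true, n_subjects = n_subjects,
                          loading_sd = loading_sd,
                          distance_decay = distance_decay,
                          rng_seed = rng_seed, ...)
  list(spaces = spaces, gt = gt)
}
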