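# small seed space over a ring + spur graph, handy for contiguity checks
ring_space <- function(n = 12L) {
  edges <- cbind(seq_len(n), c(2:n, 1L))
  seed_space(sprintf("s%02d", seq_len(n)), kind = "volume-voxel",
             hemisphere = "midline", edges = edges)
}

test_that("winner-take-all labels follow the argmax with tie-to-lowest", {
  sp <- tiny_spaces(2L)
  maps <- matrix(c(3, 0, 1, 5), 2L, byrow = TRUE)  # K=2 over 2 seeds
  p <- hard_parcellation(maps, sp$seed_space)
  expect_identical(p$labels, c(1L, 2L))
  # exact tie -> lowest component index
  p2 <- hard_parcellation(matrix(c(2, 2, 2, 2), 2L), sp$seed_space)
  expect_identical(p2$labels, c(1L, 1L))
  # shift invariance
  p3 <- hard_parcellation(maps + 7, sp$seed_space)
  expect_identical(p3$labels, p$labels)
})

test_that("excluded seeds get label zero", {
  ss <- seed_space(c("a", "b", "c"), kind = "volume-voxel",
                   hemisphere = "midline", exclusion = c(FALSE, TRUE, FALSE))
  p <- hard_parcellation(matrix(1:6, 2L), ss)
  expect_identical(p$labels[2L], 0L)
})

test_that("component matching recovers permutations and ignores sign", {
  withr::with_seed(31L, A <- matrix(rnorm(5L * 80L), 5L))
  perm <- c(3L, 1L, 5L, 2L, 4L)
  mk <- function(M) structure(list(K = 5L, gm_maps = M, wm_maps = NULL),
                              class = "tractica_components")
  m <- match_components(mk(A), mk(A[perm, ]))
  expect_identical(m$matched, order(perm))
  expect_equal(m$abs_r, rep(1, 5L), tolerance = 1e-12)
  # sign flips keep the match, signed r goes negative
  m2 <- match_components(mk(A), mk(-A))
  expect_identical(m2$matched, 1:5)
  expect_equal(m2$r, rep(-1, 5L), tolerance = 1e-12)
  expect_equal(m2$abs_r, rep(1, 5L), tolerance = 1e-12)
})

test_that("matched correlation degrades monotonically with noise", {
  withr::with_seed(32L, {
    A <- matrix(rnorm(4L * 200L), 4L)
    meds <- vapply(c(0.1, 1, 4), function(sig) {
      B <- A + matrix(rnorm(length(A), sd = sig), nrow(A))
      median(match_components(A, B)$abs_r)
    }, numeric(1L))
  })
  expect_true(all(diff(meds) < 0))
})

test_that("zero-variance maps are flagged and excluded", {
  A <- rbind(rep(1, 10), rnorm(10))
  B <- matrix(rnorm(20), 2L)
  m <- match_components(A, B)
  expect_true(m$flagged[1L])
  expect_true(is.na(m$matched[1L]))
  expect_false(m$flagged[2L])
})

test_that("dice agrees with brute-force set counting", {
  mkparc <- function(labels, K) structure(
    list(labels = as.integer(labels), K = K, source = "test"),
    class = "tractica_parcellation")
  # hand example: |S|=3, |S'|=3, overlap 2 -> 0.6667
  A <- mkparc(c(1, 1, 1, 2, 2, 2), 2L)
  B <- mkparc(c(1, 1, 2, 1, 2, 2), 2L)
  d <- dice(A, B, matching = cbind(1:2, 1:2))
  expect_equal(d$table$dice, c(2 * 2 / 6, 2 * 2 / 6), tolerance = 1e-12)

  expect_equal(dice(A, A)$mean, 1)
  disjoint <- dice(mkparc(c(1, 1, 0, 0), 1L), mkparc(c(0, 0, 1, 1), 1L),
                   matching = cbind(1L, 1L))
  expect_equal(disjoint$mean, 0)

  # randomized oracle comparison
  withr::with_seed(33L, {
    for (rep in 1:100) {
      n <- sample(20:500, 1L)
      K <- sample(2:8, 1L)
      la <- sample(0:K, n, TRUE)
      lb <- sample(0:K, n, TRUE)
      match <- cbind(1:K, sample(K))
      got <- dice(mkparc(la, K), mkparc(lb, K), matching = match)$table$dice
      want <- vapply(seq_len(K), function(i) {
        s1 <- which(la == match[i, 1L]); s2 <- which(lb == match[i, 2L])
        den <- length(s1) + length(s2)
        if (den == 0L) NA_real_ else 2 * length(intersect(s1, s2)) / den
      }, numeric(1L))
      expect_identical(got, want)
    }
  })
})

test_that("voronoi parcels are contiguous, exhaustive and deterministic", {
  sim <- default_sim(n_per_hemi = 50L, K_true = 4L)
  ss <- sim$spaces$seed_space
  p <- random_voronoi_parcellation(ss, 10L, rng_seed = 5L)
  expect_true(all(p$labels >= 1L & p$labels <= 10L))
  expect_identical(sort(unique(p$labels)), 1:10)
  # contiguity via traversal of each parcel's induced subgraph
  for (k in 1:10) {
    sub <- ss
    sub$exclusion <- p$labels != k
    comp <- tractica:::graph_components(sub)
    expect_identical(length(unique(comp[comp > 0L])), 1L)
  }
  p2 <- random_voronoi_parcellation(ss, 10L, rng_seed = 5L)
  expect_identical(p$labels, p2$labels)
  # K = n_seeds: all singletons
  pK <- random_voronoi_parcellation(ss, ss$n_seeds, rng_seed = 1L)
  expect_identical(sort(pK$labels), seq_len(ss$n_seeds))
})

test_that("disconnected graphs are refused with component sizes", {
  ss <- seed_space(c("a", "b", "c", "d"), kind = "volume-voxel",
                   hemisphere = "midline",
                   edges = rbind(c(1L, 2L), c(3L, 4L)))
  expect_error(random_voronoi_parcellation(ss, 2L), "disconnected")
})

test_that("voronoi null matches exhaustive enumeration on a 12-seed ring", {
  ss <- ring_space(12L)
  # exhaustive oracle: all unordered center pairs for both parcellations of
  # a K=2 Voronoi on a ring, BFS tie-break identical to the implementation
  centers <- utils::combn(12L, 2L)
  parcs <- lapply(seq_len(ncol(centers)), function(i)
    tractica:::voronoi_from_centers(ss, centers[, i]))
  # centers are ordered pairs in the implementation (sample order matters for
  # tie-breaks); enumerate both orders
  parcs_rev <- lapply(seq_len(ncol(centers)), function(i)
    tractica:::voronoi_from_centers(ss, rev(centers[, i])))
  all_parcs <- c(parcs, parcs_rev)
  n_p <- length(all_parcs)
  oracle_mean <- mean(vapply(seq_len(n_p * n_p), function(idx) {
    i <- (idx - 1L) %% n_p + 1L
    j <- (idx - 1L) %/% n_p + 1L
    dice(all_parcs[[i]], all_parcs[[j]])$mean
  }, numeric(1L)))
  null <- voronoi_dice_null(ss, 2L, n_iter = 300L, rng_seed = 4L)
  expect_true(all(null >= 0 & null <= 1))
  se <- sd(null) / sqrt(length(null))
  # exhaustive-pair oracle and the sampler agree within Monte-Carlo error
  expect_lt(abs(mean(null) - oracle_mean), 3 * (se + 0.01))
})

test_that("voronoi null mean decreases with dimensionality", {
  sim <- default_sim(n_per_hemi = 50L, K_true = 4L)
  ss <- sim$spaces$seed_space
  means <- vapply(c(2L, 5L, 10L), function(K)
    mean(voronoi_dice_null(ss, K, n_iter = 60L, rng_seed = 8L)), numeric(1L))
  expect_true(all(diff(means) < 0))
})

test_that("homologue correlation identifies symmetric and lateralised maps", {
  sp <- make_toy_spaces(16L, grid = c(4L, 4L, 4L))
  ss <- sp$seed_space
  n <- ss$n_seeds
  withr::with_seed(41L, half <- rexp(16L))
  symmetric <- c(half, half)           # mirrored across hemispheres
  lateral <- c(half + 3, rep(0, 16L))  # left hemisphere only
  comps <- rbind(symmetric, lateral)
  h <- homologue_correlation(comps, ss)
  expect_equal(h$r[1L], 1, tolerance = 1e-12)
  expect_identical(h$laterality[1L], "bilateral")
  # brute-force r for the lateralised map
  want <- cor(lateral, lateral[ss$homologue])
  expect_equal(h$r[2L], want, tolerance = 1e-12)
  expect_identical(h$laterality[2L], "left")
  # flip is an involution
  expect_identical(ss$homologue[ss$homologue], seq_len(n))
})

test_that("incomplete homologue maps beyond tolerance are an error", {
  sp <- make_toy_spaces(16L)
  ss <- sp$seed_space
  ss$homologue[1:8] <- NA_integer_   # 25% unmapped
  expect_error(homologue_correlation(matrix(rnorm(32), 1L), ss),
               "incomplete")
})
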