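# planted low-rank matrix with nonnegative sparse left factors
planted_matrix <- function(n = 200L, m = 600L, r = 10L, noise = 0,
                           rng_seed = 1L) {
  withr::with_seed(rng_seed, {
    U <- matrix(0, n, r)
    block <- floor(n / r)
    for (k in seq_len(r))
      U[((k - 1L) * block + 1L):(k * block), k] <- runif(block, 0.5, 1.5)
    B <- matrix(rnorm(r * m), r, m)
    X <- U %*% B
    if (noise > 0) X <- X + noise * matrix(rnorm(n * m), n, m)
    list(X = X, U = U, B = B)
  })
}

principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  # sine of the largest principal angle, computed via the residual so small
  # angles keep full precision
  resid <- qb - qa %*% crossprod(qa, qb)
  asin(min(1, svd(resid, nu = 0, nv = 0)$d[1L]))
}

test_that("MIGP recovers the exact leading subspace of a low-rank matrix", {
  p <- planted_matrix(200L, 600L, r = 10L)
  cm <- as_connmat(abs(p$X))   # connmat requires nonnegative entries
  red <- migp_reduce(cm, d = 20L, b = 150L, rng_seed = 3L)
  sv <- svd(abs(p$X), nu = 10L, nv = 0L)
  expect_lt(principal_angle(red$values[, 1:10], sv$u), 1e-8)
  expect_identical(dim(red$values), c(200L, 20L))
  # every target column consumed exactly once
  expect_identical(sort(unlist(red$visit_order)), 1:600)
})

test_that("single-block MIGP equals the exact truncated SVD factor U*S", {
  p <- planted_matrix(60L, 100L, r = 5L, noise = 0.01, rng_seed = 2L)
  X <- abs(p$X)
  cm <- as_connmat(X)
  red <- migp_reduce(cm, d = 8L, b = 100L, rng_seed = 1L)
  sv <- svd(X, nu = 8L, nv = 0L)
  US <- sv$u %*% diag(sv$d[1:8])
  # compare up to column sign
  for (j in 1:8) {
    r <- abs(cor(red$values[, j], US[, j]))
    expect_gt(r, 1 - 1e-10)
  }
})

test_that("MIGP is deterministic under a seed and stable across seeds", {
  p <- planted_matrix(80L, 300L, r = 6L, rng_seed = 4L)
  cm <- as_connmat(abs(p$X))
  r1 <- migp_reduce(cm, d = 10L, b = 60L, rng_seed = 7L)
  r2 <- migp_reduce(cm, d = 10L, b = 60L, rng_seed = 7L)
  expect_identical(r1$values, r2$values)
  r3 <- migp_reduce(cm, d = 10L, b = 60L, rng_seed = 8L)
  expect_lt(principal_angle(r1$values[, 1:6], r3$values[, 1:6]), 1e-3)
})

test_that("MIGP rejects degenerate dimensions", {
  cm <- as_connmat(matrix(1, 4, 8))
  expect_error(migp_reduce(cm, d = 5L, b = 8L), "exceeds")
  expect_error(migp_reduce(cm, d = 3L, b = 2L), "block size")
  expect_error(migp_reduce(cm, d = 0L, b = 8L), ">= 1")
})

test_that("MIGP captures at least 99% of the variance of exact rank-d SVD", {
  p <- planted_matrix(150L, 800L, r = 12L, noise = 0.05, rng_seed = 5L)
  X <- abs(p$X)
  red <- migp_reduce(as_connmat(X), d = 15L, b = 100L, rng_seed = 1L)
  Q <- qr.Q(qr(red$values))
  var_migp <- sum((crossprod(Q, X))^2)
  sv <- svd(X, nu = 0L, nv = 0L)
  var_svd <- sum(sv$d[1:15]^2)
  expect_gte(var_migp / var_svd, 0.99)
})

test_that("seed-domain ICA recovers planted independent sparse sources", {
  withr::with_seed(10L, {
    n <- 300L
    S_true <- matrix(0, 3L, n)
    S_true[1, 1:60] <- rexp(60)
    S_true[2, 101:170] <- rexp(70)
    S_true[3, 201:290] <- rexp(90)
    B <- matrix(rnorm(3L * 40L), 3L, 40L)
  })
  X <- t(S_true) %*% B   # n x 40 "reduced" matrix
  red <- structure(list(values = X, d = 40L, b = 40L), class = "tractica_reduced")
  comps <- fit_ica(red, K = 3L, rng_seed = 2L)
  m <- abs(cor(t(comps$gm_maps), t(S_true)))
  # every true source matched by some component at |r| > 0.95
  expect_true(all(apply(m, 2L, max) > 0.95))
})

test_that("K=1 on a rank-1 matrix returns the single left singular vector", {
  withr::with_seed(11L, {
    u <- rexp(120L)
    v <- rnorm(15L)
  })
  X <- u %*% t(v)
  red <- structure(list(values = X, d = 15L), class = "tractica_reduced")
  comps <- fit_ica(red, K = 1L, rng_seed = 1L)
  expect_gt(abs(cor(comps$gm_maps[1L, ], u)), 0.999)
})

test_that("ICA is equivariant under seed permutation", {
  p <- planted_matrix(90L, 200L, r = 4L, rng_seed = 12L)
  red <- migp_reduce(as_connmat(abs(p$X)), d = 6L, b = 200L, rng_seed = 1L)
  comps <- fit_ica(red, K = 4L, rng_seed = 3L)
  perm <- withr::with_seed(13L, sample.int(90L))
  red_p <- structure(list(values = red$values[perm, ], d = 6L),
                     class = "tractica_reduced")
  comps_p <- fit_ica(red_p, K = 4L, rng_seed = 3L)
  unshuffled <- comps_p$gm_maps[, order(perm)]
  # same maps up to component order/sign
  m <- abs(cor(t(comps$gm_maps), t(unshuffled)))
  expect_true(all(apply(m, 1L, max) > 1 - 1e-6))
})

test_that("gm maps respect the sign and independence conventions", {
  sim <- default_sim()
  avg <- group_average(lapply(1:6, function(s)
    sample_subject_matrix(sim$gt, s, rng_seed = 100L + s)$matrix))
  comps <- decompose_group(avg, K = 8L, rng_seed = 5L)
  skews <- apply(comps$gm_maps, 1L, function(s) mean((s - mean(s))^3))
  expect_true(all(skews >= 0))
  vars <- apply(comps$gm_maps, 1L, var)
  expect_equal(vars, rep(1, 8L), tolerance = 1e-6, ignore_attr = TRUE)
  offdiag <- cor(t(comps$gm_maps))
  diag(offdiag) <- 0
  expect_lt(max(abs(offdiag)), 0.15)
})

test_that("backprojection solves the exact linear model", {
  withr::with_seed(20L, {
    G <- matrix(rnorm(5L * 100L), 5L)
    W0 <- matrix(rnorm(5L * 40L), 5L)
  })
  M <- t(G) %*% W0
  W <- backproject(G, M, normalize = "none")
  expect_equal(W, W0, tolerance = 1e-8)
  # zero target column gives a zero coefficient column
  M2 <- cbind(M, 0)
  W2 <- backproject(G, M2, normalize = "none")
  expect_equal(W2[, 41L], rep(0, 5L), ignore_attr = TRUE)
})

test_that("orthonormal maps reduce backprojection to a projection", {
  withr::with_seed(21L, {
    G <- qr.Q(qr(matrix(rnorm(80L * 4L), 80L)))[, 1:4]
    M <- matrix(rexp(80L * 30L), 80L)
  })
  Gt <- t(G)  # 4 x 80 orthonormal rows
  expect_equal(backproject(Gt, M, normalize = "none"), Gt %*% M,
               tolerance = 1e-10)
})

test_that("collinear designs are rejected", {
  G <- rbind(rep(1, 50) + rnorm(50, sd = 1e-12), rep(1, 50))
  M <- matrix(1, 50, 10)
  expect_error(backproject(G, M, normalize = "none"), "condition")
})

test_that("decompose_group recovers all planted gm/wm pairs (noise-free)", {
  sim <- default_sim(distance_decay = 0)
  # noise-free group matrix: average of the subjects' Poisson rate matrices
  rates <- lapply(1:6, function(s) subject_rate_matrix(sim$gt, s))
  avg <- Reduce(`+`, rates) / length(rates)
  cm <- connectivity_matrix(avg, sim$spaces$seed_space,
                            sim$spaces$target_space, weighting = "averaged")
  comps <- decompose_group(cm, K = 8L, rng_seed = 6L)
  truth <- ground_truth_maps(sim$gt)
  m_gm <- abs(cor(t(truth$gm), t(comps$gm_maps)))
  best <- apply(m_gm, 1L, which.max)
  expect_true(all(apply(m_gm, 1L, max) > 0.98))
  m_wm <- vapply(1:8, function(k)
    abs(cor(truth$wm[k, ], comps$wm_maps[best[k], ])), numeric(1L))
  expect_true(all(m_wm > 0.98))
})

test_that("recovery survives Poisson noise at the default count scale", {
  sim <- default_sim(distance_decay = 0)
  mats <- lapply(1:6, function(s)
    sample_subject_matrix(sim$gt, s, rng_seed = 200L + s)$matrix)
  comps <- decompose_group(group_average(mats), K = 8L, rng_seed = 6L)
  truth <- ground_truth_maps(sim$gt)
  m_gm <- abs(cor(t(truth$gm), t(comps$gm_maps)))
  expect_gt(mean(apply(m_gm, 1L, max)), 0.9)
})

test_that("provenance round-trips through the container", {
  sim <- default_sim(n_per_hemi = 20L, K_true = 4L)
  avg <- group_average(lapply(1:3, function(s)
    sample_subject_matrix(sim$gt, s, rng_seed = s)$matrix))
  comps <- decompose_group(avg, K = 4L, rng_seed = 2L)
  path <- tempfile(fileext = ".rds")
  save_container(comps, path)
  back <- load_container(path)
  expect_identical(back$provenance, comps$provenance)
  expect_identical(back$provenance$domain, "seed")
  expect_identical(back$provenance$master_seed, 2L)
})

test_that("tract-domain decomposition swaps the independence domain", {
  sim <- default_sim(n_per_hemi = 20L, K_true = 4L)
  avg <- group_average(lapply(1:4, function(s)
    sample_subject_matrix(sim$gt, s, rng_seed = s)$matrix))
  comps <- decompose_group(avg, K = 4L, domain = "tract", rng_seed = 3L)
  expect_identical(dim(comps$gm_maps), c(4L, sim$spaces$seed_space$n_seeds))
  expect_identical(dim(comps$wm_maps),
                   c(4L, sim$spaces$target_space$n_targets))
  # independence moved to the tract domain: wm maps are less correlated than
  # their paired gm maps (the toy fingerprints themselves overlap, so a hard
  # decorrelation bound applies to the seed-domain default instead)
  od <- function(M) { C <- cor(t(M)); diag(C) <- 0; mean(abs(C)) }
  expect_lt(od(comps$wm_maps), od(comps$gm_maps))
})
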