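fake_weights <- function(n_sub = 10L, K = 3L, rng_seed = 1L) {
  withr::with_seed(rng_seed, {
    w <- expand.grid(subject = sprintf("s%02d", seq_len(n_sub)),
                     component = seq_len(K), stringsAsFactors = FALSE)
    w$gm_weight <- rnorm(nrow(w))
    w$wm_weight <- rnorm(nrow(w))
  })
  tibble::as_tibble(w)
}

test_that("spearman screen scores monotone relationships at rho = +/-1", {
  w <- fake_weights()
  cov <- data.frame(subject = sprintf("s%02d", 1:10))
  cov$same <- w$gm_weight[w$component == 1L]
  cov$cubed <- -(w$gm_weight[w$component == 1L])^3
  tab <- spearman_screen(w, cov)
  r1 <- tab[tab$weight_kind == "gm" & tab$component == 1L, ]
  expect_equal(r1$rho[r1$covariate == "same"], 1)
  expect_equal(r1$rho[r1$covariate == "cubed"], -1)
  # 2 kinds x 3 components x 2 covariates rows
  expect_identical(nrow(tab), 12L)
})

test_that("exact small-sample p-values match rank-permutation enumeration", {
  x <- c(1.2, -0.4, 2.2, 0.8, -1.9, 0.3)
  y <- c(10, 14, 7, 9, 20, 12)
  w <- tibble::tibble(subject = sprintf("s%d", 1:6),
                      component = 1L, gm_weight = x, wm_weight = x)
  tab <- spearman_screen(w, data.frame(subject = sprintf("s%d", 1:6), y = y))
  got <- tab[tab$weight_kind == "gm", ]
  # brute-force enumeration over all 720 rank permutations
  rho_obs <- cor(rank(x), rank(y))
  perms <- matrix(unlist(combinat_perms(6L)), ncol = 6L, byrow = TRUE)
  rhos <- apply(perms, 1L, function(p) cor(rank(x), p))
  p_exact <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  expect_equal(got$rho, rho_obs, tolerance = 1e-12)
  expect_equal(got$p, p_exact, tolerance = 1e-9)
})

test_that("constant covariates and short overlaps are excluded with reasons", {
  w <- fake_weights(n_sub = 8L, K = 1L)
  cov <- data.frame(subject = sprintf("s%02d", 1:8),
                    flat = rep(5, 8),
                    sparse = c(1, 2, NA, NA, NA, NA, NA, NA),
                    ok = rnorm(8))
  tab <- spearman_screen(w, cov)
  expect_identical(sort(unique(tab$covariate)), "ok")
  excl <- attr(tab, "excluded")
  expect_identical(sort(unique(excl$covariate)), c("flat", "sparse"))
  expect_match(excl$reason[excl$covariate == "sparse"][1L], "complete pairs")
})

test_that("all p = 1 yields no discoveries under either method", {
  for (m in c("storey", "bh")) {
    res <- fdr_correct(rep(1, 50L), method = m)
    expect_false(any(res$significant))
  }
  expect_error(fdr_correct(numeric()), "empty")
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
})

test_that("BH q-values agree with a brute-force step-up oracle", {
  withr::with_seed(61L, {
    for (rep in 1:100) {
      p <- runif(sample(5:200, 1L))^sample(1:3, 1L)
      got <- fdr_correct(p, method = "bh")$q
      # brute force: q_i = min over j with p_j >= p_i of p_j * m / rank_j
      m <- length(p)
      ord <- order(p)
      q_sorted <- p[ord] * m / seq_len(m)
      q_sorted <- rev(cummin(rev(q_sorted)))
      want <- numeric(m); want[ord] <- pmin(q_sorted, 1)
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("q-values are monotone in p for both methods", {
  p <- withr::with_seed(62L, c(runif(400L), runif(100L)^4))
  for (m in c("storey", "bh")) {
    q <- fdr_correct(p, method = m)$q
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-12))
  }
})

test_that("realized false discovery proportion is controlled at q < 0.05", {
  n_rep <- 200L
  fdp <- matrix(NA_real_, n_rep, 2L, dimnames = list(NULL, c("storey", "bh")))
  withr::with_seed(63L, {
    for (r in seq_len(n_rep)) {
      p <- c(rbeta(10L, 0.05, 40),   # 10 true effects
             runif(990L))            # uniform nulls
      truth <- c(rep(TRUE, 10L), rep(FALSE, 990L))
      for (m in c("storey", "bh")) {
        sig <- fdr_correct(p, method = m)$significant
        fdp[r, m] <- if (any(sig)) sum(sig & !truth) / sum(sig) else 0
      }
    }
  })
  for (m in c("storey", "bh")) {
    mean_fdp <- mean(fdp[, m])
    se <- sd(fdp[, m]) / sqrt(n_rep)
    expect_lte(mean_fdp, 0.05 + 3 * se)
  }
})

test_that("structure-function flags pairs above the 5% variance cut", {
  withr::with_seed(64L, {
    G <- matrix(rnorm(4L * 300L), 4L)
    R1 <- G[2L, ] + rnorm(300L, sd = 1e-8)  # network equal to component 2
    R2 <- rnorm(300L)                       # unrelated network
  })
  sf <- structure_function(G, rbind(R1, R2))
  expect_equal(sf$r_cut, sqrt(0.05), tolerance = 1e-12)
  expect_equal(sf$correlations[2L, 1L], 1, tolerance = 1e-6)
  expect_gte(sf$variance_explained$variance_explained[1L], 1)
  expect_true(any(sf$significant_pairs$component == 2L &
                    sf$significant_pairs$network == 1L))
  expect_identical(nrow(sf$top_pairs), 4L)  # top 2 per network
})

test_that("orthogonal functional maps yield no significant pairs", {
  withr::with_seed(65L, G <- matrix(rnorm(3L * 200L), 3L))
  # build a map orthogonal (after centering) to all three components
  b <- rnorm(200L)
  Gc <- scale(t(G), scale = FALSE)
  b <- b - mean(b)
  b <- b - Gc %*% solve(crossprod(Gc), crossprod(Gc, b))
  sf <- structure_function(G, matrix(b, 1L))
  expect_identical(nrow(sf$significant_pairs), 0L)
  expect_lt(sf$variance_explained$variance_explained[1L], 1e-12)
})

test_that("variance explained is invariant to rotation of orthogonal maps", {
  withr::with_seed(66L, {
    A <- matrix(rnorm(100L * 4L), 100L)
    f <- rnorm(100L)
    Rot <- qr.Q(qr(matrix(rnorm(16L), 4L)))
  })
  # centred orthonormal maps: rotation then preserves centring, norms and
  # mutual orthogonality, so Pearson r^2 sums are exactly invariant
  A <- sweep(A, 2L, colMeans(A))
  Q <- qr.Q(qr(A))[, 1:4]
  G1 <- t(Q)
  G2 <- Rot %*% G1
  v1 <- structure_function(G1, matrix(f, 1L))$variance_explained
  v2 <- structure_function(G2, matrix(f, 1L))$variance_explained
  expect_equal(v1$variance_explained, v2$variance_explained,
               tolerance = 1e-10)
})

test_that("the full screen plus FDR reproduces a planted association", {
  sim_w <- fake_weights(n_sub = 30L, K = 4L, rng_seed = 70L)
  cov <- data.frame(subject = sprintf("s%02d", 1:30))
  withr::with_seed(71L, {
    target <- sim_w$wm_weight[sim_w$component == 2L]
    cov$linked <- target + rnorm(30L, sd = 0.2)
    for (j in 1:20) cov[[paste0("null", j)]] <- rnorm(30L)
  })
  tab <- add_fdr(spearman_screen(sim_w, cov))
  hit <- tab[tab$weight_kind == "wm" & tab$component == 2L &
               tab$covariate == "linked", ]
  expect_true(hit$significant)
  expect_true(hit$significant_bh)
  # the planted pair is the strongest association in the table
  expect_identical(which.min(tab$p),
                   which(tab$weight_kind == "wm" & tab$component == 2L &
                           tab$covariate == "linked"))
})
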