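test_that("z-scoring standardizes columns exactly", {
  z <- zscore_columns(matrix(c(0, 1, 0, 1), ncol = 1))
  expect_equal(as.vector(z), c(-0.866, 0.866, -0.866, 0.866),
               tolerance = 1e-3)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)

  set.seed(1)
  M <- matrix(rnorm(60), ncol = 3)
  Z <- zscore_columns(M)
  expect_equal(zscore_columns(Z), Z, tolerance = 1e-12)
  expect_true(all(abs(colMeans(Z)) < 1e-12))

  M <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(zscore_columns(M), "b")
})

test_that("the cross-correlation matrix holds pairwise Pearson correlations", {
  set.seed(2)
  X <- matrix(rnorm(20 * 7), ncol = 7)
  Y <- matrix(rbinom(20 * 3, 1, 0.4), ncol = 3)
  R <- cross_correlation(zscore_columns(X), zscore_columns(Y))
  expect_identical(dim(R), c(3L, 7L))
  direct <- t(cor(X, Y))
  expect_equal(unname(R), unname(direct), tolerance = 1e-10)

  # a behavior column equal to a brain column correlates exactly 1
  Y2 <- cbind(X[, 1], Y)
  R2 <- cross_correlation(zscore_columns(X), zscore_columns(Y2))
  expect_equal(R2[1, 1], 1, tolerance = 1e-12)

  expect_error(cross_correlation(X[1:5, ], zscore_columns(Y)),
               class = "tractpls_validation_error")

  # independent columns at large n: correlations within sampling error
  set.seed(3)
  n <- 10000
  R3 <- cross_correlation(zscore_columns(matrix(rnorm(n * 4), ncol = 4)),
                          zscore_columns(matrix(rnorm(n * 2), ncol = 2)))
  expect_lt(max(abs(R3)), 3 / sqrt(n))
})

test_that("SVD components satisfy the algebraic identities", {
  # rank-1 exactness
  u <- c(0.6, -0.8)
  v <- c(1, 2, 2) / 3
  R <- 0.9 * u %*% t(v)
  comp <- svd_components(R)
  expect_equal(comp$d, c(0.9, 0), tolerance = 1e-12)

  # diagonal case
  expect_equal(svd_components(diag(c(1, 0.5)))$d, c(1, 0.5),
               tolerance = 1e-12)

  set.seed(4)
  R <- cross_correlation(zscore_columns(matrix(rnorm(30 * 12), ncol = 12)),
                         zscore_columns(matrix(rnorm(30 * 5), ncol = 5)))
  comp <- svd_components(R)
  expect_identical(comp$n_components, 5L)
  expect_equal(sum(comp$d^2), sum(R^2), tolerance = 1e-10)
  expect_equal(sum(comp$explained), 1, tolerance = 1e-12)
  recon <- t(comp$U %*% diag(comp$d) %*% comp$V)
  expect_equal(unname(t(recon)), unname(R), tolerance = 1e-10)
  # saliences are unit vectors, sign-fixed on the behavior side
  for (k in 1:5) {
    expect_equal(sum(comp$U[, k]^2), 1, tolerance = 1e-12)
    expect_equal(sum(comp$V[k, ]^2), 1, tolerance = 1e-12)
    expect_gt(comp$U[which.max(abs(comp$U[, k])), k], 0)
  }
  expect_error(svd_components(matrix(c(1, NA), 1)), "finite")
})

test_that("the leading component maximizes u'Rv over random unit probes", {
  set.seed(5)
  R <- cross_correlation(zscore_columns(matrix(rnorm(25 * 5), ncol = 5)),
                         zscore_columns(matrix(rnorm(25 * 5), ncol = 5)))
  comp <- svd_components(R)
  expect_equal(drop(t(comp$U[, 1]) %*% R %*% comp$V[1, ]), comp$d[1],
               tolerance = 1e-10)
  n_probe <- 10000
  U <- matrix(rnorm(n_probe * 5), ncol = 5)
  U <- U / sqrt(rowSums(U^2))
  V <- matrix(rnorm(n_probe * 5), ncol = 5)
  V <- V / sqrt(rowSums(V^2))
  probes <- rowSums((U %*% R) * V)
  expect_lt(max(probes), comp$d[1] + 1e-9)
})

test_that("permutation p-values are seeded, bounded, and alignment-invariant", {
  blocks <- deviation_blocks(60, latent_effect = 0, seed = 301)
  Xz <- zscore_columns(blocks$X)
  Yz <- zscore_columns(blocks$Y)
  p1 <- permutation_test(Xz, Yz, n_perm = 200, seed = 11)
  p2 <- permutation_test(Xz, Yz, n_perm = 200, seed = 11)
  expect_identical(p1, p2)
  expect_true(all(p1$p >= 1 / 201) && all(p1$p <= 1))

  # jointly permuting subjects of both blocks preserves the association:
  # the observed spectrum is unchanged exactly, the p-values up to
  # permutation-sampling noise
  idx <- sample(nrow(Xz))
  p3 <- permutation_test(Xz[idx, ], Yz[idx, ], n_perm = 200, seed = 11)
  expect_equal(p1$observed, p3$observed, tolerance = 1e-12)
  expect_lt(max(abs(p1$p - p3$p)), 4 * sqrt(0.25 / 200))

  expect_error(permutation_test(Xz, Yz, n_perm = 50),
               class = "tractpls_config_error")
})

test_that("bootstrap scores flag the planted weights in a noise-free rank-1 block", {
  set.seed(6)
  n <- 60
  wY <- c(0.75, -0.57, -0.32, 0, 0)
  wY <- wY / sqrt(sum(wY^2))
  wX <- rep(c(1, -1), length.out = 12) / sqrt(12)
  Y <- sapply(rep(0.4, 5), function(p) rbinom(n, 1, p))
  colnames(Y) <- risk_factor_names()
  score <- zscore_columns(Y) %*% wY
  X <- score %*% t(wX) + matrix(rnorm(n * 12, sd = 1e-6), ncol = 12)
  Xz <- zscore_columns(X)
  Yz <- zscore_columns(Y)
  ref <- svd_components(cross_correlation(Xz, Yz))
  bt <- bootstrap_weights(Xz, Yz, n_boot = 200, seed = 9, reference = ref)
  b1 <- bt$behavior[[1]]
  nonzero <- abs(wY) > 1e-6
  # finite-sample Gram structure of Y perturbs the saliences slightly, so
  # compare by correlation rather than entrywise
  expect_gt(abs(cor(ref$U[, 1], wY)), 0.99)
  expect_true(all(abs(b1$boot_score[nonzero]) > 1.96))
  br <- bt$brain[[1]]
  expect_true(all(abs(br$boot_score) > 1.96))

  bt2 <- bootstrap_weights(Xz, Yz, n_boot = 200, seed = 9, reference = ref)
  expect_identical(bt, bt2)
})

test_that("bootstrap scores of absent risk factors stay mostly below threshold", {
  wY <- c(uhr = 0.75, preterm = -0.57, low_baseline_iq = -0.32,
          cognitive_decline = 0, baseline_anxiety = 0)
  hits <- 0L
  runs <- 30
  for (i in seq_len(runs)) {
    blocks <- deviation_blocks(200, latent_effect = 1.5, seed = 400 + i,
                               latent_behavior_weights = wY)
    Xz <- zscore_columns(blocks$X)
    Yz <- zscore_columns(blocks$Y)
    bt <- suppressMessages(
      bootstrap_weights(Xz, Yz, n_boot = 100, seed = i))
    hits <- hits + sum(abs(bt$behavior[[1]]$boot_score[4:5]) < 1.96)
  }
  expect_gte(hits / (2 * runs), 0.9)
})

test_that("latent scores obey the singular-value covariance identity", {
  blocks <- deviation_blocks(80, latent_effect = 1, seed = 501)
  Xz <- zscore_columns(blocks$X)
  Yz <- zscore_columns(blocks$Y)
  comp <- svd_components(cross_correlation(Xz, Yz))
  sc <- latent_scores(Xz, Yz, comp)
  n <- nrow(Xz)
  for (k in seq_along(comp$d)) {
    expect_equal(sum(sc$L_X[, k] * sc$L_Y[, k]) / (n - 1), comp$d[k],
                 tolerance = 1e-10)
    expect_true(abs(sc$r[k]) <= 1 + 1e-12)
  }
  # a subject with zero brain deviations scores zero on every component
  X0 <- rbind(Xz, 0)
  expect_equal(unname((X0 %*% t(comp$V))[nrow(X0), ]), rep(0, 5))
})

test_that("the full PLS wrapper recovers a planted association end to end", {
  cors_u <- cors_v <- ps <- numeric(3)
  for (i in 1:3) {
    blocks <- deviation_blocks(200, latent_effect = 1.5, seed = 600 + i)
    res <- suppressMessages(
      pls_correlation(blocks$X, blocks$Y, n_perm = 200, n_boot = 200,
                      seed = 8))
    expect_s3_class(res, "pls_result")
    ps[i] <- res$permutation$p[1]
    cors_u[i] <- abs(cor(res$components$U[, 1],
                         blocks$truth$latent_behavior_weights))
    cors_v[i] <- abs(cor(res$components$V[1, ],
                         blocks$truth$latent_brain_weights))
    # positive latent-score correlation for the leading planted component
    expect_gt(res$scores$r[1], 0)
    if (i == 1) {
      res2 <- suppressMessages(
        pls_correlation(blocks$X, blocks$Y, n_perm = 200, n_boot = 200,
                        seed = 8))
      expect_identical(res$components, res2$components)
      expect_identical(res$bootstrap, res2$bootstrap)
    }
  }
  expect_true(all(ps < 0.05))
  expect_gte(median(cors_u), 0.9)
  expect_gte(median(cors_v), 0.9)
})
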