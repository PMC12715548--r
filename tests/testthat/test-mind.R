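test_that("feature standardization pools vertices and rejects degenerate features", {
  vt <- gen_vertex_features(4, 30, 3, seed = 21)
  zt <- zscore_features(vt)
  pooled <- do.call(rbind, zt$features)
  expect_equal(unname(colMeans(pooled)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(pooled, 2, sd)), rep(1, 3), tolerance = 1e-10)
  # idempotence
  zt2 <- zscore_features(zt)
  expect_equal(zt2$features, zt$features, tolerance = 1e-10)
  # constant feature errors by name
  vt$features <- lapply(vt$features, function(X) { X[, 2] <- 5; X })
  expect_error(zscore_features(vt), "volume")
})

test_that("gaussian_kl matches closed forms and is asymmetric", {
  expect_equal(gaussian_kl(c(0, 1), diag(2), c(0, 1), diag(2)), 0)
  # 1-D equal unit variances: KL = (mu1 - mu2)^2 / 2
  expect_equal(gaussian_kl(0, 1, 1, 1), 0.5)
  expect_equal(gaussian_kl(0, 1, 3, 1), 4.5)
  # 2-D unequal covariances: both directions, evaluated independently
  s1 <- diag(c(1, 1)); s2 <- diag(c(4, 1))
  kl_diag <- function(m1, d1, m2, d2) {
    0.5 * sum(d1 / d2 + (m2 - m1)^2 / d2 - 1 + log(d2 / d1))
  }
  expect_equal(gaussian_kl(c(0, 0), s1, c(1, 0), s2),
               kl_diag(c(0, 0), c(1, 1), c(1, 0), c(4, 1)))
  expect_equal(gaussian_kl(c(0, 0), s1, c(0, 0), s2),
               0.5 * (0.25 - 1 + log(4)))
  expect_equal(gaussian_kl(c(0, 0), s2, c(0, 0), s1),
               0.5 * (4 - 1 - log(4)))
  expect_false(isTRUE(all.equal(gaussian_kl(c(0, 0), s1, c(0, 0), s2),
                                gaussian_kl(c(0, 0), s2, c(0, 0), s1))))
  expect_error(gaussian_kl(c(0, 0), matrix(c(1, 2, 2, 1), 2), c(0, 0), diag(2)),
               "positive definite")
})

test_that("knn estimator matches the Gaussian oracle on easy cases", {
  set.seed(22)
  # identical distributions: estimate near the oracle value 0
  P <- matrix(rnorm(2000 * 2), ncol = 2)
  Q <- matrix(rnorm(2000 * 2), ncol = 2)
  expect_lt(knn_kl_estimate(P, Q, 3), 0.05)
  # 1-D unit-variance pair with KL = 0.5
  x <- matrix(rnorm(2000), ncol = 1)
  y <- matrix(rnorm(2000) + 1, ncol = 1)
  expect_lt(abs(knn_kl_estimate(x, y, 3) - 0.5), 0.15)
  # P == Q exactly: duplicate-distance jitter path, clamped at 0
  expect_identical(knn_kl_estimate(P, P, 3), 0)
  expect_error(knn_kl_estimate(P[1:3, ], Q, 3), "smaller than")
})

test_that("MIND matrices respect divergence axioms and the 1/(1+D) transform", {
  vt <- gen_vertex_features(8, 60, 3, seed = 23)
  mm <- mind_matrix(vt, estimator = "gaussian")
  v <- mm$values
  expect_identical(mm$kind, "mind_raw")
  expect_equal(unname(diag(v)), rep(1, 8))
  expect_true(all(v > 0 & v <= 1))
  expect_identical(v, t(v))
  # arithmetic of the transform on the true divergences
  expect_equal(vt$true_mind[vt$true_kl == 0], rep(1, sum(vt$true_kl == 0)))
  expect_equal(unname(1 / (1 + 1)), 0.5) # D = 1 maps to 0.5 by definition

  # z-normalized variant: signed, lower triangle standardized
  mz <- mind_matrix(vt, estimator = "gaussian", znorm = TRUE)
  lt <- lower_triangle(mz)
  expect_identical(mz$kind, "mind_znorm")
  expect_equal(mean(lt), 0, tolerance = 1e-10)
  expect_equal(sd(lt), 1, tolerance = 1e-10)
  expect_identical(mz$values, t(mz$values))
})

test_that("region permutation equivariance holds", {
  vt <- gen_vertex_features(6, 40, 3, seed = 24)
  mm <- mind_matrix(vt, estimator = "gaussian")
  perm <- c(3, 1, 6, 2, 5, 4)
  vtp <- vt
  vtp$features <- vt$features[perm]
  vtp$region_labels <- vt$region_labels[perm]
  mmp <- mind_matrix(vtp, estimator = "gaussian")
  expect_equal(unname(mmp$values), unname(mm$values[perm, perm]), tolerance = 1e-12)
})

test_that("MIND decreases as two regions diverge (monotonicity)", {
  # move region 2 away from region 1 in steps; the pair's MIND must not rise
  vals <- sapply(c(0, 0.5, 1, 2), function(shift) {
    vt <- gen_vertex_features(4, 200, 3, separation = 0, seed = 25)
    vt$features[[2]] <- vt$features[[2]] + shift
    mind_matrix(vt, estimator = "gaussian", standardize = FALSE)$values[2, 1]
  })
  expect_true(all(diff(vals) <= 0))
  expect_equal(vals[1], 1, tolerance = 0.15) # identical distributions: MIND near 1
})

test_that("knn estimator error shrinks with sample size toward the oracle", {
  truth <- gaussian_kl(c(0, 0), diag(2), c(1, 1), diag(2))
  errs <- sapply(c(200, 1000, 5000), function(n) {
    median(sapply(1:20, function(s) {
      set.seed(s)
      P <- matrix(rnorm(n * 2), ncol = 2)
      Q <- matrix(rnorm(n * 2), ncol = 2) + 1
      abs(knn_kl_estimate(P, Q, 3) - truth)
    }))
  })
  expect_true(all(diff(errs) < 0))
})
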