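test_that("lower-triangle vectorization and reconstruction round-trip", {
  expect_length(lower_triangle(matrix(0, 3, 3)), 3)
  expect_length(lower_triangle(matrix(0, 400, 400)), 79800)
  set.seed(51)
  m <- matrix(rnorm(64), 8); m <- m + t(m); diag(m) <- 0
  expect_equal(mirror_lower(lower_triangle(m), 8), m)
  expect_error(lower_triangle(matrix(0, 2, 3)), "square")
})

test_that("factor correspondence agrees with a direct-summation oracle", {
  set.seed(52)
  mk <- function() { m <- matrix(rnorm(100), 10); m <- m + t(m); diag(m) <- 0; m }
  a <- mk()
  tab_self <- factor_correspondence(list(a), list(a, neg = -a))
  expect_equal(tab_self$r[1], 1)
  expect_equal(tab_self$r[2], -1)

  for (i in 1:50) {
    x <- mk(); y <- mk()
    tab <- factor_correspondence(list(x), list(y))
    expect_equal(tab$r, pearson_oracle(lower_triangle(x), lower_triangle(y)),
                 tolerance = 1e-12)
  }
  # symmetry in arguments up to transposition
  b <- mk()
  t1 <- factor_correspondence(list(f1 = a, f2 = b), list(g = mk()))
  expect_equal(t1$n_edges, rep(45, 2))
})

test_that("loading-behavior correlations handle exact and missing data", {
  set.seed(53)
  ld <- factorscape:::rdirichlet(40, 1, k = 3)
  colnames(ld) <- paste0("f", 1:3)
  beh <- data.frame(copy = ld[, 1], noise = rnorm(40))
  tab <- loading_behavior_correlations(ld, beh)
  expect_equal(tab$r[tab$factor == "f1" & tab$scale == "copy"], 1)
  expect_equal(tab$n, rep(40, 6))
  # pairwise deletion bookkeeping
  beh$copy[1:20] <- NA
  tab2 <- loading_behavior_correlations(ld, beh)
  expect_equal(tab2$n[tab2$scale == "copy"], rep(20, 3))
  # under 3 complete pairs: flagged, not computed
  beh$copy[1:38] <- NA
  tab3 <- loading_behavior_correlations(ld, beh)
  expect_true(all(is.na(tab3$r[tab3$scale == "copy"])))
})

test_that("null behavior effects give nominal type-I error", {
  rej <- sapply(1:300, function(i) {
    set.seed(600 + i)
    ld <- factorscape:::rdirichlet(50, 0.5, k = 3)
    beh <- gen_behavior(ld, matrix(0, 1, 3, dimnames = list("null_scale", NULL)),
                        noise_sd = 1, seed = 900 + i)
    any(loading_behavior_correlations(ld, beh)$p[1] < 0.05)
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("PCA summary recovers rank-1 structure with the sign convention", {
  set.seed(54)
  v <- rnorm(12)
  pc <- pca_first_component(tcrossprod(v))
  expect_equal(abs(cor(pc, v)), 1, tolerance = 1e-10)
  # sign fixed against row means
  m <- tcrossprod(v) + matrix(rnorm(144, sd = 0.1), 12)
  m <- (m + t(m)) / 2
  pc2 <- pca_first_component(m)
  expect_gte(cor(pc2, rowMeans(m)), 0)
  # PC1 dominates PC2
  pr <- prcomp(m)
  expect_gte(pr$sdev[1], pr$sdev[2])
  expect_error(pca_first_component(matrix(1, 4, 4)), "rank 0")
})

test_that("receptor regression matches the normal-equations oracle", {
  sph <- gen_sphere_parcellation(60, seed = 55)
  for (i in 1:50) {
    atlas <- gen_receptor_maps(sph, 5, smoothness = 1, seed = 2000 + i)
    set.seed(3000 + i)
    pc <- rnorm(60)
    fit <- receptor_regression(pc, atlas)
    X <- cbind(1, scale(atlas$densities))
    beta_oracle <- solve(t(X) %*% X, t(X) %*% as.vector(scale(pc)))
    expect_equal(fit$beta, unname(beta_oracle[-1]), tolerance = 1e-10)
  }
  # single map equal to the pc: beta 1, perfect fit
  atlas1 <- gen_receptor_maps(sph, 1, smoothness = 1, seed = 56)
  fit1 <- receptor_regression(atlas1$densities[, 1], atlas1)
  expect_equal(fit1$beta, 1, tolerance = 1e-10)
  expect_equal(attr(fit1, "r_squared"), 1, tolerance = 1e-10)
  # response orthogonal to all maps: betas vanish
  atlas2 <- gen_receptor_maps(sph, 3, smoothness = 0, seed = 57)
  q <- qr.Q(qr(cbind(1, atlas2$densities)), complete = TRUE)[, 5]
  expect_equal(receptor_regression(q, atlas2)$beta, rep(0, 3), tolerance = 1e-10)
  # collinear maps rejected with the offending pair named
  dens <- atlas2$densities
  dens <- cbind(dens, dup = dens[, 1] + 1e-9 * rnorm(60))
  expect_error(receptor_regression(q, dens), "collinear")
})

test_that("spin null rows are within-hemisphere permutations", {
  sph <- gen_sphere_parcellation(40, seed = 58)
  null <- build_spin_null(sph, 50, seed = 59)
  left <- which(sph$hemisphere == "L")
  right <- which(sph$hemisphere == "R")
  for (p in seq_len(50)) {
    expect_identical(sort(null$perms[p, ]), 1:40)
    expect_true(all(null$perms[p, left] %in% left))
    expect_true(all(null$perms[p, right] %in% right))
  }
  # identity rotation maps every parcel to itself
  expect_identical(factorscape:::spin_assignment(sph, diag(3)), 1:40)
})

test_that("spins preserve the spatial autocorrelation of smooth maps", {
  sph <- gen_sphere_parcellation(200, seed = 60)
  null <- build_spin_null(sph, 100, seed = 61)
  atlas <- gen_receptor_maps(sph, 4, smoothness = 2, seed = 62)
  nn1 <- hemisphere_nn1(sph)
  lag1 <- function(m) mean(sapply(seq_len(ncol(m)), function(j) cor(m[, j], m[nn1, j])))
  orig <- lag1(atlas$densities)
  spun <- mean(sapply(seq_len(100), function(p) {
    lag1(atlas$densities[null$perms[p, ], , drop = FALSE])
  }))
  # spun maps retain most of the lag-1 autocorrelation; a uniform random
  # permutation destroys it entirely
  rand <- mean(sapply(1:20, function(s) {
    set.seed(s)
    lag1(atlas$densities[sample(200), , drop = FALSE])
  }))
  expect_gt(orig, 0.6)
  expect_gt(spun / orig, 0.8)
  expect_lt(abs(rand), 0.15)
})

test_that("spin p-values respect the add-one floor and flag true signal", {
  sph <- gen_sphere_parcellation(400, seed = 63)
  null <- build_spin_null(sph, 200, seed = 64)
  atlas <- gen_receptor_maps(sph, 19, smoothness = 2, seed = 65)
  set.seed(66)
  pc <- atlas$densities[, "CB1"] + rnorm(400, sd = 0.1)
  tab <- spin_pvalues(pc, atlas, null)
  expect_true(all(tab$p_spin > 0 & tab$p_spin <= 1))
  expect_gte(min(tab$p_spin), 1 / 201) # add-one rule floor
  expect_equal(tab$p_spin[tab$transmitter == "CB1"], 1 / 201)
  expect_warning(spin_pvalues(pc, atlas, build_spin_null(sph, 50, seed = 67)),
                 "fewer than 100")
})
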