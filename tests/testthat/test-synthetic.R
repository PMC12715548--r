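test_that("sphere parcellation gives unit vectors, hemisphere split, determinism", {
  sph <- gen_sphere_parcellation(4, seed = 1)
  expect_equal(sqrt(rowSums(sph$coords^2)), rep(1, 4), tolerance = 1e-12)

  sph400 <- gen_sphere_parcellation(400, seed = 2)
  expect_equal(sum(sph400$hemisphere == "L"), 200)
  expect_equal(sum(sph400$hemisphere == "R"), 200)

  expect_identical(gen_sphere_parcellation(20, seed = 5)$coords,
                   gen_sphere_parcellation(20, seed = 5)$coords)
  expect_error(gen_sphere_parcellation(7), "even")
  expect_error(gen_sphere_parcellation(2), "even")
})

test_that("factor truth matrices are symmetric, sign-mixed, and well separated", {
  f1 <- gen_factor_truth(1, 10, edge_density = 1, seed = 3)
  expect_identical(f1[[1]], t(f1[[1]]))
  expect_true(all(lower_triangle(f1[[1]]) != 0)) # density 1 => fully dense
  expect_equal(diag(f1[[1]]), rep(0, 10))

  fs <- gen_factor_truth(3, 20, seed = 4)
  lt <- sapply(fs, lower_triangle)
  cc <- cor(lt)
  expect_lt(max(abs(cc[lower.tri(cc)])), 0.5)
  expect_true(all(sapply(fs, function(m) any(m > 0) && any(m < 0))))

  expect_error(gen_factor_truth(3, 20, edge_density = 0), "edge_density")
  expect_error(gen_factor_truth(3, 20, edge_density = 1.5), "edge_density")
})

test_that("cohort matrices are exact mixtures in the noiseless limit", {
  truth <- gen_factor_truth(3, 10, seed = 5)
  ld <- matrix(c(1, 0, 0,
                 0.2, 0.5, 0.3), 2, 3, byrow = TRUE)
  coh <- suppressWarnings( # N = 2 < K on purpose: exact loadings supplied
    gen_cohort_matrices(truth, 2, noise_sd = 0, seed = 6, loadings = ld))
  expect_equal(coh$matrices[[1]], truth[[1]])
  expect_equal(coh$matrices[[2]],
               0.2 * truth[[1]] + 0.5 * truth[[2]] + 0.3 * truth[[3]])
})

test_that("cohort loadings live on the simplex and track the concentration", {
  truth <- gen_factor_truth(3, 10, seed = 7)
  lo <- gen_cohort_matrices(truth, 1000, dirichlet_alpha = 0.1, seed = 8)$loadings
  hi <- gen_cohort_matrices(truth, 1000, dirichlet_alpha = 10, seed = 9)$loadings
  expect_equal(unname(rowSums(lo)), rep(1, 1000), tolerance = 1e-12)
  expect_true(all(lo >= 0))
  # low concentration pushes mass to the simplex vertices
  expect_gt(mean(apply(lo, 1, max)), mean(apply(hi, 1, max)))
  # symmetry of generated subject matrices survives noise
  m <- gen_cohort_matrices(truth, 3, noise_sd = 0.2, seed = 10)$matrices[[2]]
  expect_identical(m, t(m))
  expect_warning(gen_cohort_matrices(truth, 2, seed = 11), "not identifiable")
})

test_that("vertex features carry a valid closed-form divergence target", {
  vt <- gen_vertex_features(6, 30, 5, separation = 1, seed = 12)
  expect_equal(vt$feature_names,
               c("thickness", "volume", "area", "curvature", "sulcal_depth"))
  expect_identical(vt$true_kl, t(vt$true_kl))
  expect_true(all(vt$true_kl >= 0))
  expect_equal(unname(diag(vt$true_kl)), rep(0, 6))

  # separation 0: all regions share one Gaussian, zero divergence
  vt0 <- gen_vertex_features(5, 30, 3, separation = 0, seed = 13)
  expect_equal(max(vt0$true_kl), 0)

  expect_error(gen_vertex_features(5, 4, 5), "vertices_per_region")
})

test_that("generated time series recover their target correlation", {
  ts <- gen_timeseries(diag(8), 10000, seed = 14)
  r <- cor(ts)
  expect_lt(max(abs(r[row(r) != col(r)])), 0.05)

  expect_identical(gen_timeseries(diag(4), 50, seed = 15),
                   gen_timeseries(diag(4), 50, seed = 15))
  bad <- matrix(1, 3, 3) # rank 1 is fine; break PSD instead
  bad[1, 2] <- bad[2, 1] <- -1
  expect_error(gen_timeseries(bad, 100), "eigenvalue")
  expect_warning(gen_timeseries(diag(3), 2, seed = 16), "rank-deficient|degenerate")
})

test_that("receptor maps are standardized and smoothing induces autocorrelation", {
  sph <- gen_sphere_parcellation(100, seed = 17)
  atlas <- gen_receptor_maps(sph, 19, smoothness = 2, seed = 18)
  expect_equal(ncol(atlas$densities), 19)
  expect_equal(unname(colMeans(atlas$densities)), rep(0, 19), tolerance = 1e-10)
  expect_equal(unname(apply(atlas$densities, 2, sd)), rep(1, 19), tolerance = 1e-10)

  nn1 <- hemisphere_nn1(sph)
  lag1 <- function(m) mean(sapply(seq_len(ncol(m)), function(j) cor(m[, j], m[nn1, j])))
  rough <- mean(sapply(1:25, function(s) {
    lag1(gen_receptor_maps(sph, 4, smoothness = 0, seed = 200 + s)$densities)
  }))
  smooth <- lag1(atlas$densities)
  expect_lt(abs(rough), 0.1) # no smoothing: neighbours uncorrelated
  expect_gt(smooth, 0.5)
})

test_that("behavior scores follow the linear coupling model", {
  ld <- factorscape:::rdirichlet(50, 1, k = 3)
  eff <- diag(3)
  rownames(eff) <- c("a", "b", "c")
  beh <- gen_behavior(ld, eff, noise_sd = 0, seed = 19)
  expect_equal(unname(as.matrix(beh)), unname(ld)) # identity effects, no noise

  # strong effect, small noise: strong sample correlation at N = 100
  ld2 <- factorscape:::rdirichlet(100, 0.5, k = 3)
  eff2 <- matrix(c(1, 0, 0), 1, 3, dimnames = list("s1", NULL))
  beh2 <- gen_behavior(ld2, eff2, noise_sd = 0.1, seed = 20)
  expect_gt(cor(ld2[, 1], beh2$s1), 0.5)

  expect_error(gen_behavior(ld, matrix(0, 2, 2), 1), "columns")
})
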