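# Small shared fixtures, built in code at test time.

# A tiny well-separated ground truth + cohort for factorization tests.
make_small_cohort <- function(K = 3, R = 12, N = 40, seed = 101,
                              noise_sd = 0.05, alpha = 0.5) {
  truth <- gen_factor_truth(K, R, edge_density = 0.3, seed = seed)
  cohort <- gen_cohort_matrices(truth, N, alpha, noise_sd, seed = seed + 1)
  list(truth = truth, matrices = cohort$matrices, loadings = cohort$loadings)
}

# Independent direct-summation Pearson correlation (oracle for cor-based
# operations; no calls into stats::cor).
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- sum(x * y) - sx * sy / n
  den <- sqrt((sum(x^2) - sx^2 / n) * (sum(y^2) - sy^2 / n))
  num / den
}

# Within-hemisphere nearest-neighbour index for spatial lag-1 statistics.
hemisphere_nn1 <- function(sphere) {
  R <- nrow(sphere$coords)
  nn1 <- integer(R)
  for (h in unique(sphere$hemisphere)) {
    idx <- which(sphere$hemisphere == h)
    D <- as.matrix(stats::dist(sphere$coords[idx, , drop = FALSE]))
    diag(D) <- Inf
    nn1[idx] <- idx[apply(D, 1, which.min)]
  }
  nn1
}
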