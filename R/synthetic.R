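# Synthetic cohort generator. Every input the pipeline consumes can be
# generated here with known ground truth: signed factor matrices, Dirichlet
# subject loadings, Gaussian vertex clouds with closed-form divergences,
# spatially autocorrelated receptor maps on a sphere, and behavior scores
# linearly coupled to the true loadings. All generators are deterministic
# given (parameters, seed).

# Quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Generate a spherical parcellation with hemisphere labels
#'
#' Places `R/2` parcel centroids per hemisphere as a quasi-uniform
#' Fibonacci lattice on the unit sphere, each hemisphere independently
#' rotated by a random orientation. This mimics cortical parcellations
#' after spherical inflation: each hemisphere is its own complete sphere
#' (as in FreeSurfer's per-hemisphere registration) tiled by roughly
#' equal-area parcels. The first half of the parcels is labeled left, the
#' second half right. The coordinates feed the spin-permutation null and
#' the receptor-map smoother, both of which operate within hemisphere.
#'
#' @param R Even number of regions, at least 4.
#' @param seed Integer seed.
#' @return A `sphere_parcellation`: list with `coords` (R x 3 unit rows),
#'   `hemisphere` (`"L"`/`"R"`), and `labels`.
#' @export
gen_sphere_parcellation <- function(R, seed = 1) {
  if (R %% 2 != 0 || R < 4) {
    stop("`R` must be an even integer >= 4 (half per hemisphere)", call. = FALSE)
  }
  set.seed(seed)
  half <- R / 2
  pts <- rbind(fibonacci_sphere(half) %*% t(random_rotation()),
               fibonacci_sphere(half) %*% t(random_rotation()))
  structure(list(coords = pts,
                 hemisphere = rep(c("L", "R"), each = half),
                 labels = default_region_labels(R)),
            class = "sphere_parcellation")
}

#' Generate ground-truth signed factor matrices
#'
#' Draws `K` symmetric zero-diagonal matrices whose nonzero edges are a mix
#' of positive ("hyper") and negative ("hypo") values. Edge supports lean
#' disjoint across factors (already-used edges are down-weighted when
#' sampling the next support) and draws are rejected until all pairwise
#' lower-triangle correlations are below 0.5, so that the factors are
#' identifiable in recovery experiments.
#'
#' @param K Number of factors (>= 1).
#' @param R Number of regions.
#' @param edge_density Fraction of lower-triangle edges that are nonzero per
#'   factor, in (0, 1].
#' @param magnitude Standard deviation of nonzero edge values.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling cap for the separation constraint.
#' @return List of `K` symmetric `R x R` matrices.
#' @export
gen_factor_truth <- function(K, R, edge_density = 0.25, magnitude = 1,
                             seed = 1, max_tries = 100) {
  if (K < 1) stop("`K` must be >= 1", call. = FALSE)
  if (edge_density <= 0 || edge_density > 1) {
    stop("`edge_density` must be in (0, 1]", call. = FALSE)
  }
  E <- n_edges(R)
  m_edges <- max(1L, round(edge_density * E))
  set.seed(seed)
  for (try in seq_len(max_tries)) {
    w <- rep(1, E)
    edge_vecs <- matrix(0, E, K)
    for (k in seq_len(K)) {
      sel <- sample.int(E, m_edges, prob = w)
      w[sel] <- 0.05
      vals <- stats::rnorm(m_edges, sd = magnitude)
      if (m_edges >= 2 && length(unique(sign(vals))) == 1) {
        vals[1] <- -vals[1] # guarantee both channels are represented
      }
      edge_vecs[sel, k] <- vals
    }
    ok <- TRUE
    if (K > 1) {
      cc <- suppressWarnings(stats::cor(edge_vecs))
      cc[is.na(cc)] <- 0
      ok <- max(abs(cc[lower.tri(cc)])) < 0.5
    }
    if (ok) {
      return(lapply(seq_len(K), function(k) mirror_lower(edge_vecs[, k], R)))
    }
  }
  stop("could not generate factors with pairwise |r| < 0.5; lower edge_density or raise R",
       call. = FALSE)
}

#' Generate a cohort of subject matrices as noisy factor mixtures
#'
#' Each subject matrix is `sum_k loading_k * factor_k` plus symmetric
#' Gaussian edge noise, with loadings drawn from a Dirichlet distribution
#' (or supplied explicitly for controlled experiments). This is the
#' generative assumption under which latent-factor recovery is testable.
#'
#' @param factor_matrices List of K symmetric ground-truth matrices.
#' @param N Number of subjects.
#' @param dirichlet_alpha Dirichlet concentration, scalar or length K (> 0).
#' @param noise_sd Standard deviation of edge noise (>= 0).
#' @param seed Integer seed.
#' @param loadings Optional N x K matrix of loadings to use instead of
#'   Dirichlet draws (rows must lie on the simplex).
#' @return List with `matrices` (length-N list of symmetric matrices) and
#'   `loadings` (N x K matrix, rows summing to 1).
#' @export
gen_cohort_matrices <- function(factor_matrices, N, dirichlet_alpha = 0.5,
                                noise_sd = 0.05, seed = 1, loadings = NULL) {
  K <- length(factor_matrices)
  R <- nrow(factor_matrices[[1]])
  if (any(dirichlet_alpha <= 0)) stop("`dirichlet_alpha` must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (N < K) warning("N < K: factor recovery is not identifiable", call. = FALSE)
  set.seed(seed)
  if (is.null(loadings)) {
    loadings <- rdirichlet(N, dirichlet_alpha, k = K)
  } else {
    loadings <- as.matrix(loadings)
    stopifnot(nrow(loadings) == N, ncol(loadings) == K,
              all(loadings >= 0), max(abs(rowSums(loadings) - 1)) < 1e-8)
  }
  E <- n_edges(R)
  fac_edges <- vapply(factor_matrices, lower_triangle, numeric(E))
  mats <- lapply(seq_len(N), function(i) {
    edges <- as.vector(fac_edges %*% loadings[i, ])
    if (noise_sd > 0) edges <- edges + stats::rnorm(E, sd = noise_sd)
    mirror_lower(edges, R)
  })
  rownames(loadings) <- sprintf("subject_%03d", seq_len(N))
  colnames(loadings) <- sprintf("factor_%d", seq_len(K))
  list(matrices = mats, loadings = loadings)
}

#' Generate vertex-level morphometric features with known divergences
#'
#' Each region is a cloud of i.i.d. draws from a region-specific
#' multivariate Gaussian; `separation` scales both the spread of region
#' means and the departure of region covariances from identity, so
#' `separation = 0` makes all regions share one Gaussian (all true
#' divergences zero). Returns the closed-form symmetrized-KL matrix between
#' the true Gaussians as the recovery target, plus its inverse-divergence
#' transform.
#'
#' @param R Number of regions.
#' @param vertices_per_region Vertices per region (>= n_features + 2).
#' @param n_features Number of morphometric features (default 5: thickness,
#'   volume, area, curvature, sulcal depth).
#' @param separation Scale of between-region differences (>= 0).
#' @param seed Integer seed.
#' @return A `vertex_feature_table`: list with `features` (list of
#'   V x F matrices), `feature_names`, `region_labels`, plus ground truth
#'   `true_kl` (symmetrized, nats), `true_mind` = 1/(1+KL), and the true
#'   `means`/`covs`.
#' @export
gen_vertex_features <- function(R, vertices_per_region = 200, n_features = 5,
                                separation = 1, seed = 1) {
  F <- n_features
  if (F < 1) stop("`n_features` must be >= 1", call. = FALSE)
  if (vertices_per_region < F + 2) {
    stop(sprintf("`vertices_per_region` must be >= n_features + 2 (= %d) for covariance estimation",
                 F + 2), call. = FALSE)
  }
  if (separation < 0) stop("`separation` must be >= 0", call. = FALSE)
  set.seed(seed)
  feature_names <- if (F <= 5) {
    c("thickness", "volume", "area", "curvature", "sulcal_depth")[seq_len(F)]
  } else {
    sprintf("feature_%d", seq_len(F))
  }
  w <- min(0.3, 0.3 * separation) # covariance departure from identity
  means <- vector("list", R)
  covs <- vector("list", R)
  feats <- vector("list", R)
  for (r in seq_len(R)) {
    means[[r]] <- stats::rnorm(F, sd = separation)
    Wr <- matrix(stats::rnorm(F * F), F, F)
    covs[[r]] <- (1 - w) * diag(F) + w * tcrossprod(Wr) / F
    Lr <- chol(covs[[r]])
    Z <- matrix(stats::rnorm(vertices_per_region * F), ncol = F)
    X <- Z %*% Lr + rep(means[[r]], each = vertices_per_region)
    colnames(X) <- feature_names
    feats[[r]] <- X
  }
  true_kl <- matrix(0, R, R)
  for (i in seq_len(R)) {
    for (j in seq_len(R)) {
      if (j < i) {
        d <- (gaussian_kl(means[[i]], covs[[i]], means[[j]], covs[[j]]) +
              gaussian_kl(means[[j]], covs[[j]], means[[i]], covs[[i]])) / 2
        true_kl[i, j] <- true_kl[j, i] <- d
      }
    }
  }
  labels <- default_region_labels(R)
  dimnames(true_kl) <- list(labels, labels)
  structure(list(features = feats,
                 feature_names = feature_names,
                 region_labels = labels,
                 true_kl = true_kl,
                 true_mind = 1 / (1 + true_kl),
                 means = means, covs = covs),
            class = "vertex_feature_table")
}

#' Generate BOLD-like time series with a given population correlation
#'
#' Draws `n_timepoints` i.i.d. multivariate Gaussian samples whose
#' population correlation matrix equals `target_fc`; the sample FC converges
#' to the target as T grows.
#'
#' @param target_fc Symmetric positive semi-definite matrix with unit
#'   diagonal.
#' @param n_timepoints Number of timepoints T.
#' @param seed Integer seed.
#' @return T x R numeric matrix with region-label column names.
#' @export
gen_timeseries <- function(target_fc, n_timepoints, seed = 1) {
  target_fc <- sim_values(target_fc)
  if (!is_symmetric_tol(target_fc, 1e-8)) {
    stop("`target_fc` must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(target_fc) - 1)) > 1e-8) {
    stop("`target_fc` must have unit diagonal", call. = FALSE)
  }
  ev <- eigen((target_fc + t(target_fc)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop(sprintf("`target_fc` is not positive semi-definite (smallest eigenvalue %.3g)",
                 min(ev$values)), call. = FALSE)
  }
  if (n_timepoints < 3) {
    warning("n_timepoints < 3: sample correlation is rank-deficient/degenerate",
            call. = FALSE)
  }
  root <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  set.seed(seed)
  R <- nrow(target_fc)
  ts <- matrix(stats::rnorm(n_timepoints * R), ncol = R) %*% root
  colnames(ts) <- if (!is.null(colnames(target_fc))) colnames(target_fc) else default_region_labels(R)
  ts
}

# Project a symmetric matrix onto the correlation matrices (PSD, unit
# diagonal) by eigenvalue clipping followed by renormalization. Used to turn
# "base + factor mixture" patterns into valid FC sampling targets.
#' Nearest-correlation projection by eigenvalue clipping
#'
#' @param m Symmetric matrix.
#' @param eps Floor for eigenvalues.
#' @return A valid correlation matrix (PSD, unit diagonal).
#' @export
nearest_correlation <- function(m, eps = 1e-6) {
  m <- (m + t(m)) / 2
  diag(m) <- 1
  ev <- eigen(m, symmetric = TRUE)
  vals <- pmax(ev$values, eps)
  out <- ev$vectors %*% (vals * t(ev$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  out
}

#' Generate spatially autocorrelated receptor density maps
#'
#' Each map starts as i.i.d. Gaussian noise over parcels and is smoothed by
#' repeated averaging over each parcel's k nearest neighbours on its
#' hemisphere sphere (`smoothness` rounds; 0 = no smoothing) — hemispheres
#' are independent spheres, so smoothing never crosses the midline. Maps are
#' standardized to zero mean and unit variance. Map names follow the 19
#' PET-derived transmitter maps commonly used for cortical annotation
#' (NET, CB1, ...).
#'
#' @param sphere A [gen_sphere_parcellation()] object.
#' @param n_maps Number of maps (default 19).
#' @param smoothness Non-negative number of smoothing rounds.
#' @param seed Integer seed.
#' @param k_neighbors Neighbourhood size for smoothing.
#' @return A `receptor_atlas`: list with `densities` (R x n_maps,
#'   standardized columns) and the `sphere`.
#' @export
gen_receptor_maps <- function(sphere, n_maps = 19, smoothness = 2, seed = 1,
                              k_neighbors = 6) {
  stopifnot(inherits(sphere, "sphere_parcellation"))
  if (smoothness < 0) stop("`smoothness` must be >= 0", call. = FALSE)
  R <- nrow(sphere$coords)
  set.seed(seed)
  x <- matrix(stats::rnorm(R * n_maps), R, n_maps)
  rounds <- round(smoothness)
  if (rounds > 0) {
    # cap the neighbourhood well below the hemisphere size so smoothing
    # cannot collapse a small parcellation's maps to constants
    k_eff <- min(k_neighbors, max(1L, (min(table(sphere$hemisphere)) - 1L) %/% 2L))
    nn <- matrix(0L, R, k_eff)
    for (h in unique(sphere$hemisphere)) {
      idx <- which(sphere$hemisphere == h)
      D <- as.matrix(stats::dist(sphere$coords[idx, , drop = FALSE]))
      nn[idx, ] <- matrix(idx[t(apply(D, 1, function(d) order(d)[2:(k_eff + 1)]))],
                          ncol = k_eff)
    }
    for (s in seq_len(rounds)) {
      sm <- vapply(seq_len(R), function(i) {
        colMeans(x[c(i, nn[i, ]), , drop = FALSE])
      }, numeric(n_maps))
      x <- if (n_maps == 1) matrix(sm, ncol = 1) else t(sm)
    }
  }
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  transmitter_names <- c("5HT1a", "5HT1b", "5HT2a", "5HT4", "5HT6", "5HTT",
                         "A4B2", "CB1", "D1", "D2", "DAT", "GABAa", "H3",
                         "M1", "mGluR5", "MOR", "NET", "NMDA", "VAChT")
  colnames(x) <- if (n_maps <= 19) transmitter_names[seq_len(n_maps)] else sprintf("map_%02d", seq_len(n_maps))
  rownames(x) <- sphere$labels
  structure(list(densities = x, sphere = sphere), class = "receptor_atlas")
}

#' Generate behavior scores linearly coupled to true loadings
#'
#' `score_s = loadings %*% effects_s + Gaussian noise`, one column per
#' behavioral scale. Zero-effect scales give exact nulls for calibration
#' experiments.
#'
#' @param true_loadings N x K loading matrix.
#' @param effects S x K matrix of linear coefficients; row names become
#'   scale names.
#' @param noise_sd Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Data frame of N rows x S scale columns (plus subject ids as row
#'   names).
#' @export
gen_behavior <- function(true_loadings, effects, noise_sd = 1, seed = 1) {
  true_loadings <- as.matrix(true_loadings)
  effects <- as.matrix(effects)
  if (ncol(effects) != ncol(true_loadings)) {
    stop(sprintf("`effects` must have K = %d columns (got %d)",
                 ncol(true_loadings), ncol(effects)), call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  set.seed(seed)
  N <- nrow(true_loadings)
  S <- nrow(effects)
  scores <- true_loadings %*% t(effects)
  if (noise_sd > 0) scores <- scores + matrix(stats::rnorm(N * S, sd = noise_sd), N, S)
  scale_names <- rownames(effects)
  if (is.null(scale_names)) scale_names <- sprintf("scale_%d", seq_len(S))
  out <- as.data.frame(scores)
  names(out) <- scale_names
  rownames(out) <- if (!is.null(rownames(true_loadings))) rownames(true_loadings) else sprintf("subject_%03d", seq_len(N))
  out
}
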