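# Morphometric Inverse Divergence (MIND). Each cortical region is treated as
# a multivariate distribution of its vertices over F morphometric features;
# similarity between two regions is 1/(1 + D) where D is the symmetrized
# Kullback-Leibler divergence between the two distributions, estimated either
# in closed form under a Gaussian model or nonparametrically by k-NN density
# ratios.

#' Standardize morphometric features across a subject's pooled vertices
#'
#' Each feature column is z-scored over the pooled vertex set of all
#' regions, so that features on incommensurate units (mm, mm^2, ...)
#' contribute comparably to the divergence. Idempotent within floating
#' point.
#'
#' @param table A `vertex_feature_table` (see [gen_vertex_features()] for
#'   the structure: `features` is a list of V x F matrices).
#' @return The table with standardized feature matrices.
#' @export
zscore_features <- function(table) {
  stopifnot(inherits(table, "vertex_feature_table") || is.list(table))
  feats <- table$features
  counts <- vapply(feats, nrow, integer(1))
  pooled <- do.call(rbind, feats)
  mu <- colMeans(pooled)
  sd_ <- apply(pooled, 2, stats::sd)
  if (any(sd_ == 0)) {
    bad <- table$feature_names[sd_ == 0]
    stop(sprintf("feature(s) with zero variance across pooled vertices: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  pooled <- sweep(sweep(pooled, 2, mu), 2, sd_, "/")
  idx <- cumsum(c(0L, counts))
  table$features <- lapply(seq_along(feats), function(r) {
    out <- pooled[(idx[r] + 1):idx[r + 1], , drop = FALSE]
    colnames(out) <- table$feature_names
    out
  })
  table
}

#' Closed-form KL divergence between two multivariate Gaussians
#'
#' `KL(P || Q) = 1/2 [ tr(S2^-1 S1) + (m2-m1)' S2^-1 (m2-m1) - F
#'  + ln(det S2 / det S1) ]` in nats. Serves both as the fast estimation
#' path (Gaussian model per region) and as the exact oracle for the
#' nonparametric estimator.
#'
#' @param mean1,cov1 Mean vector and covariance of P.
#' @param mean2,cov2 Mean vector and covariance of Q.
#' @return Nonnegative divergence in nats.
#' @export
gaussian_kl <- function(mean1, cov1, mean2, cov2) {
  cov1 <- as.matrix(cov1); cov2 <- as.matrix(cov2)
  F <- length(mean1)
  stopifnot(length(mean2) == F, all(dim(cov1) == F), all(dim(cov2) == F))
  ch1 <- tryCatch(chol(cov1), error = function(e) NULL)
  ch2 <- tryCatch(chol(cov2), error = function(e) NULL)
  if (is.null(ch1) || is.null(ch2)) {
    stop("covariance matrix is not positive definite", call. = FALSE)
  }
  inv2 <- chol2inv(ch2)
  delta <- mean2 - mean1
  logdet1 <- 2 * sum(log(diag(ch1)))
  logdet2 <- 2 * sum(log(diag(ch2)))
  kl <- 0.5 * (sum(inv2 * cov1) + drop(t(delta) %*% inv2 %*% delta) - F +
                 logdet2 - logdet1)
  max(kl, 0)
}

#' Nonparametric k-NN Kullback-Leibler divergence estimate
#'
#' Density-ratio estimator of Wang, Kulkarni & Verdu:
#' `(F/n) * sum_i log(nu_k(i) / rho_k(i)) + log(m / (n-1))`, where
#' `rho_k(i)` is the k-th NN distance of sample i within P (self excluded)
#' and `nu_k(i)` its k-th NN distance into Q. The estimate can be slightly
#' negative at finite n and is clamped at 0. Zero distances arising from
#' duplicate points are replaced by the smallest positive distance observed
#' times 1e-6 (deterministic).
#'
#' @param samples_p n x F sample matrix from P.
#' @param samples_q m x F sample matrix from Q.
#' @param k Neighbour order (default 3); must be < min(n, m).
#' @return Nonnegative divergence estimate in nats.
#' @export
knn_kl_estimate <- function(samples_p, samples_q, k = 3) {
  samples_p <- as.matrix(samples_p)
  samples_q <- as.matrix(samples_q)
  n <- nrow(samples_p); m <- nrow(samples_q); F <- ncol(samples_p)
  if (ncol(samples_q) != F) stop("sample sets must share the feature count", call. = FALSE)
  if (k >= min(n, m)) {
    stop(sprintf("`k` (%d) must be smaller than both sample sizes (%d, %d)", k, n, m),
         call. = FALSE)
  }
  rho <- kth_nn_dist(samples_p, samples_p, as.integer(k), TRUE)
  nu <- kth_nn_dist(samples_p, samples_q, as.integer(k), FALSE)
  all_d <- c(rho, nu)
  if (any(all_d == 0)) {
    pos <- all_d[all_d > 0]
    if (length(pos) == 0) return(0) # all points identical: zero divergence
    jit <- min(pos) * 1e-6
    rho[rho == 0] <- jit
    nu[nu == 0] <- jit
  }
  est <- (F / n) * sum(log(nu / rho)) + log(m / (n - 1))
  max(est, 0)
}

# Per-region Gaussian fits (mean + sample covariance) for the closed-form path.
region_gaussians <- function(feats) {
  lapply(feats, function(X) list(mean = colMeans(X), cov = stats::cov(X)))
}

#' Compute a MIND similarity matrix from vertex features
#'
#' For every region pair the symmetrized divergence
#' `D = (KL(P||Q) + KL(Q||P)) / 2` is estimated and mapped to
#' `MIND = 1/(1 + D)` in (0, 1] with unit diagonal. With `znorm = TRUE`
#' the off-diagonal values are z-scored over the lower triangle, mirrored
#' back, and the diagonal set to the maximum z (display only; excluded from
#' all statistics), giving a signed `mind_znorm` matrix.
#'
#' @param table A `vertex_feature_table`.
#' @param estimator `"knn"` (nonparametric, default) or `"gaussian"`
#'   (closed form on per-region Gaussian fits).
#' @param k Neighbour order for the knn estimator.
#' @param znorm Z-normalize the similarity values?
#' @param standardize Apply [zscore_features()] first (default TRUE).
#' @return A [similarity_matrix()] of kind `mind_raw` or `mind_znorm`.
#' @export
mind_matrix <- function(table, estimator = c("knn", "gaussian"), k = 3,
                        znorm = FALSE, standardize = TRUE) {
  estimator <- match.arg(estimator)
  feats <- table$features
  R <- length(feats)
  F <- ncol(feats[[1]])
  if (any(vapply(feats, nrow, integer(1)) < F + 2)) {
    stop("every region needs at least n_features + 2 vertices", call. = FALSE)
  }
  if (standardize) {
    table <- zscore_features(table)
    feats <- table$features
  }
  D <- matrix(0, R, R)
  if (estimator == "gaussian") {
    g <- region_gaussians(feats)
    for (i in seq_len(R)) {
      for (j in seq_len(i - 1L)) {
        d <- (gaussian_kl(g[[i]]$mean, g[[i]]$cov, g[[j]]$mean, g[[j]]$cov) +
              gaussian_kl(g[[j]]$mean, g[[j]]$cov, g[[i]]$mean, g[[i]]$cov)) / 2
        D[i, j] <- D[j, i] <- d
      }
    }
  } else {
    for (i in seq_len(R)) {
      for (j in seq_len(i - 1L)) {
        d <- (knn_kl_estimate(feats[[i]], feats[[j]], k) +
              knn_kl_estimate(feats[[j]], feats[[i]], k)) / 2
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  mind <- 1 / (1 + D)
  diag(mind) <- 1
  labels <- table$region_labels
  if (is.null(labels)) labels <- default_region_labels(R)
  if (!znorm) {
    return(similarity_matrix(mind, "mind_raw", labels))
  }
  lt <- lower_triangle(mind)
  if (stats::sd(lt) == 0) stop("cannot z-normalize a constant similarity matrix", call. = FALSE)
  z <- (lt - mean(lt)) / stats::sd(lt)
  zm <- mirror_lower(z, R, diag_value = max(z))
  similarity_matrix(zm, "mind_znorm", labels)
}
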