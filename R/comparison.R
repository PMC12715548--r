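# Factor characterization: lower-triangle correspondence between factor
# matrices, loading-behavior correlations, PCA summarization of factors to
# region vectors, receptor-map regression, and the spin-permutation spatial
# null for cortical maps.

#' All-pairs lower-triangle correspondence between two factor lists
#'
#' Pearson correlation (with two-sided p) between the vectorized lower
#' triangles of every pair of matrices, e.g. patient-derived factors versus
#' the healthy-control group-average pattern, or structure (MIND) versus
#' function (FC) factors.
#'
#' @param factors_a,factors_b `factor_set`s or (named) lists of symmetric
#'   matrices on the same parcellation.
#' @return Data frame with columns `factor_a`, `factor_b`, `r`, `p`,
#'   `n_edges`.
#' @export
factor_correspondence <- function(factors_a, factors_b) {
  ma <- extract_matrices(factors_a)
  mb <- extract_matrices(factors_b)
  names_a <- names(ma)
  if (is.null(names_a)) names_a <- sprintf("a%d", seq_along(ma))
  names_b <- names(mb)
  if (is.null(names_b)) names_b <- sprintf("b%d", seq_along(mb))
  out <- expand.grid(factor_a = names_a, factor_b = names_b,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- t(mapply(function(i, j) {
    x <- lower_triangle(ma[[i]])
    y <- lower_triangle(mb[[j]])
    ct <- stats::cor.test(x, y)
    c(r = unname(ct$estimate), p = ct$p.value, n_edges = length(x))
  },
  rep(seq_along(ma), times = length(mb)),
  rep(seq_along(mb), each = length(ma))))
  cbind(out, as.data.frame(res))
}

#' Correlate subject loadings with behavioral scores
#'
#' Pairwise-complete Pearson correlation between every factor loading and
#' every behavioral scale, with a two-sided t-test p-value and the number of
#' complete pairs per cell. Cells with fewer than 3 complete pairs are
#' flagged and left uncomputed.
#'
#' @param loadings N x K loading matrix.
#' @param behavior Data frame or matrix of N rows x S numeric scales,
#'   subject-aligned with `loadings`.
#' @return Data frame with columns `factor`, `scale`, `r`, `p`, `n`.
#' @export
loading_behavior_correlations <- function(loadings, behavior) {
  loadings <- as.matrix(loadings)
  behavior <- as.data.frame(behavior)
  if (nrow(behavior) != nrow(loadings)) {
    stop("`behavior` and `loadings` must have the same number of subjects", call. = FALSE)
  }
  fac_names <- colnames(loadings)
  if (is.null(fac_names)) fac_names <- sprintf("factor_%d", seq_len(ncol(loadings)))
  rows <- list()
  for (k in seq_len(ncol(loadings))) {
    for (s in seq_along(behavior)) {
      x <- loadings[, k]
      y <- behavior[[s]]
      ok <- stats::complete.cases(x, y)
      n <- sum(ok)
      if (n < 3) {
        rows[[length(rows) + 1]] <- data.frame(
          factor = fac_names[k], scale = names(behavior)[s],
          r = NA_real_, p = NA_real_, n = n)
        next
      }
      ct <- stats::cor.test(x[ok], y[ok])
      rows[[length(rows) + 1]] <- data.frame(
        factor = fac_names[k], scale = names(behavior)[s],
        r = unname(ct$estimate), p = ct$p.value, n = n)
    }
  }
  do.call(rbind, rows)
}

#' First principal component of a symmetric matrix over regions
#'
#' Treats the R x R matrix as R observations (rows = regions) over R
#' variables, column-centers it, and returns the first principal component
#' scores: one summary value per region describing the dominant pattern of
#' that factor's connectivity profile. The sign is fixed so the component
#' correlates nonnegatively with the matrix row means.
#'
#' @param m Symmetric matrix or [similarity_matrix()].
#' @return Numeric vector of length R (named by region if labels exist).
#' @export
pca_first_component <- function(m) {
  v <- sim_values(m)
  stopifnot(is.matrix(v), nrow(v) == ncol(v))
  centered <- scale(v, center = TRUE, scale = FALSE)
  if (max(abs(centered)) == 0) stop("matrix has rank 0 after centering", call. = FALSE)
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)$x[, 1]
  rm_ <- rowMeans(v)
  if (stats::sd(rm_) > 0 && stats::sd(pc) > 0 &&
      stats::cor(pc, rm_) < 0) {
    pc <- -pc
  }
  names(pc) <- rownames(v)
  pc
}

receptor_design <- function(atlas) {
  X <- scale(as.matrix(if (inherits(atlas, "receptor_atlas")) atlas$densities else atlas))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  X
}

#' Regress a factor summary vector on receptor density maps
#'
#' Ordinary least squares with the PC summary vector (standardized) as
#' response and all M standardized receptor maps as joint predictors,
#' returning standardized betas and R^2. A `"simple"` variant fits M
#' separate single-map regressions instead.
#'
#' @param pc Region summary vector (length R).
#' @param atlas A `receptor_atlas` or an R x M density matrix.
#' @param method `"joint"` (default, one model with M predictors) or
#'   `"simple"`.
#' @return A `receptor_regression`: data frame with `transmitter`, `beta`
#'   plus attributes `r_squared`, `intercept`, `method`.
#' @export
receptor_regression <- function(pc, atlas, method = c("joint", "simple")) {
  method <- match.arg(method)
  X <- receptor_design(atlas)
  M <- ncol(X)
  R <- nrow(X)
  if (length(pc) != R) stop("`pc` length must match the atlas parcellation", call. = FALSE)
  if (R <= M + 1) stop("need more regions than predictors (R > M + 1)", call. = FALSE)
  sv <- svd(X, nu = 0, nv = 0)$d
  cond <- (sv[1] / sv[length(sv)])^2
  if (!is.finite(cond) || cond > 1e8) {
    cc <- stats::cor(X)
    bad <- which(abs(cc) > 0.999 & row(cc) > col(cc), arr.ind = TRUE)
    pairs <- apply(bad, 1, function(ij) paste(colnames(X)[ij], collapse = " ~ "))
    stop(sprintf("receptor maps are collinear (condition number %.3g); offending pairs: %s",
                 cond, paste(pairs, collapse = ", ")), call. = FALSE)
  }
  y <- as.vector(scale(pc))
  if (method == "joint") {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
    betas <- fit$coefficients[-1]
    intercept <- fit$coefficients[1]
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  } else {
    betas <- vapply(seq_len(M), function(j) {
      stats::lm.fit(cbind(1, X[, j]), y)$coefficients[2]
    }, numeric(1))
    names(betas) <- colnames(X)
    intercept <- 0
    r2 <- NA_real_
  }
  out <- data.frame(transmitter = colnames(X), beta = unname(betas))
  attr(out, "r_squared") <- r2
  attr(out, "intercept") <- unname(intercept)
  attr(out, "method") <- method
  class(out) <- c("receptor_regression", "data.frame")
  out
}

random_rotation <- function() {
  Z <- matrix(stats::rnorm(9), 3, 3)
  qrz <- qr(Z)
  Q <- qr.Q(qrz)
  Q <- Q %*% diag(sign(diag(qr.R(qrz))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# For one rotation, build the within-hemisphere permutation: the left
# hemisphere is rotated by `rot`, the right by its x-mirror, and each
# rotated parcel is reassigned to an original parcel by greedy unique
# nearest-neighbour matching (ascending distance), yielding a true
# permutation per hemisphere.
spin_assignment <- function(sphere, rot) {
  mirror <- diag(c(-1, 1, 1))
  R <- nrow(sphere$coords)
  perm <- integer(R)
  for (h in unique(sphere$hemisphere)) {
    idx <- which(sphere$hemisphere == h)
    P <- sphere$coords[idx, , drop = FALSE]
    rot_h <- if (h == "L") rot else mirror %*% rot %*% mirror
    Q <- P %*% t(rot_h)
    D <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * tcrossprod(P, Q)
    ord <- order(D)
    n_h <- length(idx)
    pos_free <- rep(TRUE, n_h)
    src_free <- rep(TRUE, n_h)
    assigned <- 0L
    for (o in ord) {
      i <- (o - 1L) %% n_h + 1L  # original position
      j <- (o - 1L) %/% n_h + 1L # rotated parcel
      if (pos_free[i] && src_free[j]) {
        perm[idx[i]] <- idx[j]
        pos_free[i] <- FALSE
        src_free[j] <- FALSE
        assigned <- assigned + 1L
        if (assigned == n_h) break
      }
    }
  }
  perm
}

#' Build a spin-permutation null for cortical maps
#'
#' Each permutation draws a uniform random 3-D rotation, applies it to the
#' left hemisphere and its mirror image to the right, and reassigns rotated
#' parcels to original parcels by greedy unique nearest-neighbour matching.
#' Every null row is therefore a true within-hemisphere permutation of
#' region indices, preserving each map's value multiset while approximately
#' preserving its spatial autocorrelation.
#'
#' @param sphere A [gen_sphere_parcellation()] object.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return A `spin_null`: list with `perms` (n_perm x R index matrix),
#'   `n_perm`, `seed`.
#' @export
build_spin_null <- function(sphere, n_perm = 1000, seed = 1) {
  stopifnot(inherits(sphere, "sphere_parcellation"))
  R <- nrow(sphere$coords)
  set.seed(seed)
  perms <- matrix(0L, n_perm, R)
  for (p in seq_len(n_perm)) {
    perms[p, ] <- spin_assignment(sphere, random_rotation())
  }
  structure(list(perms = perms, n_perm = n_perm, seed = seed),
            class = "spin_null")
}

#' Spin-permutation p-values for receptor regression betas
#'
#' Recomputes the joint regression betas after permuting the response (the
#' factor summary vector) by each spin and reports two-sided empirical
#' p-values `(1 + #{|beta_perm| >= |beta_obs|}) / (n_perm + 1)` per
#' transmitter, plus Benjamini-Hochberg q-values. Permuting the response is
#' equivalent to rotating the whole predictor set and much cheaper.
#'
#' @param pc Region summary vector.
#' @param atlas A `receptor_atlas` or density matrix.
#' @param null A [build_spin_null()] object on the same parcellation.
#' @return Data frame with `transmitter`, `beta`, `p_spin`, `q_bh`; attribute
#'   `r_squared` from the observed fit.
#' @export
spin_pvalues <- function(pc, atlas, null) {
  stopifnot(inherits(null, "spin_null"))
  if (null$n_perm < 100) {
    warning("fewer than 100 spin permutations: p-values are coarse", call. = FALSE)
  }
  X <- receptor_design(atlas)
  R <- nrow(X)
  if (ncol(null$perms) != R) stop("spin null built on a different parcellation", call. = FALSE)
  obs <- receptor_regression(pc, atlas, method = "joint")
  y <- as.vector(scale(pc))
  design <- cbind(1, X)
  qr_x <- qr(design)
  Yperm <- matrix(y[t(null$perms)], nrow = R) # R x n_perm, column per spin
  B <- qr.coef(qr_x, Yperm)[-1, , drop = FALSE] # M x n_perm
  p <- vapply(seq_len(nrow(B)), function(j) {
    (1 + sum(abs(B[j, ]) >= abs(obs$beta[j]))) / (null$n_perm + 1)
  }, numeric(1))
  out <- data.frame(transmitter = obs$transmitter, beta = obs$beta,
                    p_spin = p, q_bh = stats::p.adjust(p, method = "BH"))
  attr(out, "r_squared") <- attr(obs, "r_squared")
  out
}
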