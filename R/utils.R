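# Shared low-level helpers: lower-triangle vectorization in a fixed canonical
# order, simplex draws, and the similarity-matrix container used by every
# downstream stage.

# Canonical edge order for an R-region parcellation: row-major over the strict
# lower triangle, i.e. (2,1), (3,1), (3,2), (4,1), ... All vectorized edges,
# LDA vocabularies and factor matrices use this order.
lt_index <- function(R) {
  ij <- which(lower.tri(matrix(0L, R, R)), arr.ind = TRUE)
  ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
}

#' Vectorize the strict lower triangle of a square matrix
#'
#' Returns the `R(R-1)/2` off-diagonal entries of a symmetric matrix in the
#' package's canonical row-major order `(2,1), (3,1), (3,2), ...` The diagonal
#' is always excluded. This is the vectorization used everywhere a matrix is
#' compared or turned into an edge document.
#'
#' @param m A square matrix or a [similarity_matrix()] object.
#' @return Numeric vector of length `R(R-1)/2`.
#' @export
lower_triangle <- function(m) {
  v <- sim_values(m)
  if (!is.matrix(v) || nrow(v) != ncol(v)) {
    stop("`m` must be a square matrix", call. = FALSE)
  }
  v[lt_index(nrow(v))]
}

#' Rebuild a symmetric matrix from a lower-triangle vector
#'
#' Inverse of [lower_triangle()]: mirrors the edge vector into a symmetric
#' matrix with a constant diagonal.
#'
#' @param edges Edge vector in canonical lower-triangle order.
#' @param R Number of regions.
#' @param diag_value Value placed on the diagonal (default 0).
#' @return Symmetric `R x R` matrix.
#' @export
mirror_lower <- function(edges, R, diag_value = 0) {
  stopifnot(length(edges) == R * (R - 1) / 2)
  m <- matrix(0, R, R)
  m[lt_index(R)] <- edges
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

n_edges <- function(R) R * (R - 1L) / 2L

# Half-away-from-zero rounding, fixed across platforms (round() is
# half-to-even and would make document counts platform-sensitive in spirit).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

is_symmetric_tol <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

# Dirichlet draws via normalized gammas; alpha recycled to length k.
rdirichlet <- function(n, alpha, k = length(alpha)) {
  alpha <- rep_len(alpha, k)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  s <- rowSums(g)
  # guard against numeric underflow at very small alpha
  bad <- s == 0
  if (any(bad)) {
    g[bad, ] <- 0
    g[cbind(which(bad), max.col(matrix(stats::runif(sum(bad) * k), ncol = k)))] <- 1
    s <- rowSums(g)
  }
  g / s
}

default_region_labels <- function(R) sprintf("region_%03d", seq_len(R))

#' Similarity matrix container
#'
#' A light S3 wrapper holding a symmetric region-by-region matrix together
#' with its kind tag and region labels. Kinds: `mind_raw` (inverse-divergence
#' similarity in (0,1], diagonal 1), `mind_znorm` (z-normalized MIND, signed),
#' `fc_r` (Pearson correlation, diagonal 1), `fc_z` (Fisher-z units,
#' diagonal 0 by convention).
#'
#' @param values Symmetric numeric matrix (within 1e-10).
#' @param kind One of `"mind_raw"`, `"mind_znorm"`, `"fc_r"`, `"fc_z"`.
#' @param labels Optional region labels (defaults to `region_001`, ...).
#' @return An object of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, kind, labels = NULL) {
  kind <- match.arg(kind, c("mind_raw", "mind_znorm", "fc_r", "fc_z"))
  if (!is_symmetric_tol(values, 1e-10)) {
    stop("similarity matrix must be symmetric within 1e-10", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  R <- nrow(values)
  if (is.null(labels)) labels <- default_region_labels(R)
  stopifnot(length(labels) == R)
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, kind = kind, labels = labels),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix: %s, %d x %d regions>\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Accept either a bare matrix or a similarity_matrix wherever convenient.
sim_values <- function(x) {
  if (inherits(x, "similarity_matrix")) x$values else x
}

sim_kind <- function(x) {
  if (inherits(x, "similarity_matrix")) x$kind else NA_character_
}
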