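# Functional connectivity: Pearson correlation between parcellated BOLD time
# series, Fisher r-to-z run averaging, and group averaging for the healthy
# control comparison pattern.

#' Functional connectivity from a parcellated time series
#'
#' Pearson correlation between all region pairs of a T x R time-series
#' matrix.
#'
#' @param ts T x R numeric matrix (T >= 3), columns named by region.
#' @return A [similarity_matrix()] of kind `fc_r` (unit diagonal).
#' @export
fc_from_timeseries <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("time series needs at least 3 timepoints", call. = FALSE)
  if (anyNA(ts)) stop("time series contains missing values", call. = FALSE)
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0)) {
    labels <- colnames(ts)
    if (is.null(labels)) labels <- default_region_labels(ncol(ts))
    stop(sprintf("zero temporal variance in region(s): %s",
                 paste(labels[sds == 0], collapse = ", ")), call. = FALSE)
  }
  r <- stats::cor(ts)
  labels <- colnames(ts)
  similarity_matrix(r, "fc_r", labels)
}

#' Fisher r-to-z transform and its inverse
#'
#' `z = atanh(r)`; `r = tanh(z)`. The forward direction requires |r| < 1.
#'
#' @param r Correlations with |r| < 1.
#' @return Fisher-z values.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) {
    stop("fisher_z requires |r| < 1; clip near-unit correlations first", call. = FALSE)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher-z values.
#' @export
inverse_fisher <- function(z) tanh(z)

#' Average functional connectivity across runs in Fisher-z space
#'
#' Each run's off-diagonal correlations are Fisher r-to-z transformed and the
#' z matrices averaged element-wise. The diagonal (r = 1 maps to infinity) is
#' excluded from the transform and set to 0 in the output; off-diagonal
#' values within 1e-12 of +/-1 (finite-precision duplicates) are clipped to
#' +/-(1 - 1e-7) with a warning. The result stays in z units.
#'
#' @param matrices List of `fc_r` [similarity_matrix()] objects with
#'   identical region labels.
#' @return A [similarity_matrix()] of kind `fc_z` (zero diagonal).
#' @export
average_runs <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  labels <- matrices[[1]]$labels
  for (m in matrices) {
    if (!inherits(m, "similarity_matrix") || m$kind != "fc_r") {
      stop("average_runs expects fc_r similarity matrices", call. = FALSE)
    }
    if (!identical(m$labels, labels)) {
      stop("region labels differ across runs", call. = FALSE)
    }
  }
  R <- length(labels)
  acc <- matrix(0, R, R)
  for (m in matrices) {
    v <- m$values
    off <- v[row(v) != col(v)]
    near_one <- abs(abs(off) - 1) <= 1e-12
    if (any(near_one)) {
      warning(sprintf("%d off-diagonal correlation(s) at |r| ~ 1 clipped to 1 - 1e-7",
                      sum(near_one)), call. = FALSE)
      v[row(v) != col(v) & abs(abs(v) - 1) <= 1e-12] <-
        sign(v[row(v) != col(v) & abs(abs(v) - 1) <= 1e-12]) * (1 - 1e-7)
    }
    z <- v
    z[row(z) != col(z)] <- atanh(v[row(v) != col(v)])
    diag(z) <- 0
    acc <- acc + z
  }
  similarity_matrix(acc / length(matrices), "fc_z", labels)
}

#' Element-wise group average of similarity matrices
#'
#' The arithmetic mean across subjects, used as the healthy-control
#' comparison pattern for both FC and MIND.
#'
#' @param matrices List of at least two [similarity_matrix()] objects of the
#'   same kind with identical region labels.
#' @return A [similarity_matrix()] of the shared kind.
#' @export
group_average <- function(matrices) {
  if (length(matrices) < 2) stop("group_average needs at least 2 subjects", call. = FALSE)
  kinds <- vapply(matrices, sim_kind, character(1))
  if (length(unique(kinds)) != 1 || anyNA(kinds)) {
    stop("all matrices must be similarity_matrix objects of the same kind", call. = FALSE)
  }
  labels <- matrices[[1]]$labels
  for (m in matrices) {
    if (!identical(m$labels, labels)) stop("region labels differ across subjects", call. = FALSE)
  }
  acc <- Reduce(`+`, lapply(matrices, sim_values)) / length(matrices)
  similarity_matrix(acc, kinds[1], labels)
}
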