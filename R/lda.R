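# Latent factor decomposition of signed similarity/connectivity matrices via
# smoothed latent Dirichlet allocation. Each subject matrix becomes a "count
# document" over a vocabulary of 2E words (E lower-triangle edges, each split
# into a positive "hyper" and a negative "hypo" channel); variational EM
# yields K factor word distributions (rendered as signed matrices) and
# per-subject simplex loadings.

document_from_edges <- function(edges, scale, subject_id = NULL) {
  E <- length(edges)
  pos <- round_half_away(scale * pmax(edges, 0))
  neg <- round_half_away(scale * pmax(-edges, 0))
  w <- c(pos, neg) # words 1..E: positive channel; E+1..2E: negative channel
  ids <- which(w > 0)
  if (length(ids) == 0) {
    stop("document has zero total count after rounding; increase `scale`", call. = FALSE)
  }
  structure(list(ids = as.integer(ids), counts = as.numeric(w[ids]),
                 total = sum(w), n_words = 2L * E, subject_id = subject_id),
            class = "count_document")
}

#' Convert a signed similarity matrix into an edge count document
#'
#' Each lower-triangle value x contributes `round(scale * max(x, 0))` counts
#' to the edge's positive-channel word and `round(scale * max(-x, 0))` to its
#' negative-channel word (half-away-from-zero rounding). At most one channel
#' per edge is nonzero.
#'
#' @param m Symmetric matrix or [similarity_matrix()].
#' @param scale Positive count scale (default 10).
#' @param subject_id Optional id stored with the document.
#' @return A `count_document` with sparse `ids`/`counts` over the 2E
#'   vocabulary.
#' @export
matrix_to_document <- function(m, scale = 10, subject_id = NULL) {
  if (scale <= 0) stop("`scale` must be > 0", call. = FALSE)
  document_from_edges(lower_triangle(m), scale, subject_id)
}

#' Build an LDA corpus from a cohort of matrices
#'
#' Optionally z-scores each edge across the cohort before count conversion
#' (`center = "zscore_edges"`), for parity with frameworks that normalize by
#' a reference group. The default is no centering: patient matrices enter
#' the factorization unnormalized.
#'
#' @param matrices List of symmetric matrices / [similarity_matrix()]s.
#' @param scale Count scale passed to [matrix_to_document()].
#' @param center `"none"` (default) or `"zscore_edges"`.
#' @param subject_ids Optional character vector of ids.
#' @return List of `count_document`s.
#' @export
build_corpus <- function(matrices, scale = 10, center = c("none", "zscore_edges"),
                         subject_ids = NULL) {
  center <- match.arg(center)
  edge_mat <- t(vapply(matrices, lower_triangle,
                       numeric(n_edges(nrow(sim_values(matrices[[1]]))))))
  if (center == "zscore_edges") {
    edge_mat <- scale(edge_mat)
    edge_mat[is.na(edge_mat)] <- 0 # constant edges carry no signal
  }
  if (is.null(subject_ids)) subject_ids <- sprintf("subject_%03d", seq_along(matrices))
  lapply(seq_along(matrices), function(i) {
    document_from_edges(edge_mat[i, ], scale, subject_ids[i])
  })
}

digamma_rows <- function(m) digamma(m) - digamma(rowSums(m))

# Full variational bound for smoothed LDA (corpus log evidence lower bound),
# evaluated at the current variational parameters gamma (N x K) and lambda
# (K x W) with document-level phi implicitly optimized.
lda_bound <- function(docs, gamma, lambda, alpha, eta) {
  K <- ncol(gamma); W <- ncol(lambda); N <- nrow(gamma)
  ElogTheta <- digamma_rows(gamma)
  ElogBeta <- digamma_rows(lambda)
  score <- 0
  for (d in seq_len(N)) {
    ids <- docs[[d]]$ids
    cts <- docs[[d]]$counts
    M <- ElogTheta[d, ] + ElogBeta[, ids, drop = FALSE] # K x nw
    mx <- apply(M, 2, max)
    score <- score + sum(cts * (log(colSums(exp(M - rep(mx, each = K)))) + mx))
  }
  # E[log p(theta | alpha)] - E[log q(theta | gamma)]
  score <- score + sum((alpha - gamma) * ElogTheta) +
    sum(lgamma(gamma)) - sum(lgamma(rowSums(gamma))) +
    N * (lgamma(K * alpha) - K * lgamma(alpha))
  # E[log p(beta | eta)] - E[log q(beta | lambda)]
  score <- score + sum((eta - lambda) * ElogBeta) +
    sum(lgamma(lambda)) - sum(lgamma(rowSums(lambda))) +
    K * (lgamma(W * eta) - W * lgamma(eta))
  score
}

fit_lda_once <- function(docs, K, alpha, eta, max_iter, tol, seed) {
  W <- docs[[1]]$n_words
  N <- length(docs)
  set.seed(seed)
  lambda <- matrix(stats::rgamma(K * W, shape = 100, rate = 100), K, W)
  gamma <- matrix(alpha + docs[[1]]$total / K, N, K)
  bounds <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ElogBeta <- digamma_rows(lambda)
    eEB <- exp(ElogBeta)
    sstats <- matrix(0, K, W)
    for (d in seq_len(N)) {
      ids <- docs[[d]]$ids
      cts <- docs[[d]]$counts
      B <- eEB[, ids, drop = FALSE]
      gam <- rep(alpha + docs[[d]]$total / K, K)
      eET <- exp(digamma(gam) - digamma(sum(gam)))
      phinorm <- as.vector(crossprod(B, eET)) + 1e-100
      for (it in seq_len(100)) {
        gam_new <- alpha + eET * as.vector(B %*% (cts / phinorm))
        delta <- mean(abs(gam_new - gam))
        gam <- gam_new
        eET <- exp(digamma(gam) - digamma(sum(gam)))
        phinorm <- as.vector(crossprod(B, eET)) + 1e-100
        if (delta < 1e-6) break
      }
      gamma[d, ] <- gam
      sstats[, ids] <- sstats[, ids] + (eET * B) * rep(cts / phinorm, each = K)
    }
    lambda <- eta + sstats
    bounds <- c(bounds, lda_bound(docs, gamma, lambda, alpha, eta))
    if (iter > 1) {
      rel <- abs(bounds[iter] - bounds[iter - 1]) / abs(bounds[iter - 1])
      if (rel < tol) {
        converged <- TRUE
        break
      }
    }
  }
  list(lambda = lambda, gamma = gamma, bounds = bounds,
       converged = converged, iterations = length(bounds), seed = seed)
}

#' Fit a smoothed LDA factor model to an edge-document corpus
#'
#' Variational EM for latent Dirichlet allocation with a symmetric Dirichlet
#' prior `alpha` on per-subject factor proportions and `eta` on factor word
#' distributions. Runs `n_restarts` independent random initializations and
#' returns the restart with the best final evidence lower bound (ELBO). The
#' ELBO trace is non-decreasing within numerical slack by construction and is
#' stored in the fit metadata. Deterministic given `seed`.
#'
#' @param documents List of `count_document`s (at least K).
#' @param K Number of factors.
#' @param alpha Loading concentration (default `50/K`, standard topic-model
#'   practice).
#' @param eta Word-distribution smoothing (default 0.01).
#' @param n_restarts Number of random restarts (default 5).
#' @param max_iter Maximum EM iterations per restart (default 200).
#' @param tol Relative ELBO change convergence threshold (default 1e-5).
#' @param seed Integer seed; restart r uses `seed + r - 1`.
#' @return List with `factors` (a `factor_set`: `K`, `word_distributions`
#'   K x 2E, `signed_matrices`), `loadings` (N x K simplex rows), and
#'   `metadata` (bound trace, restart index, convergence/monotonicity flags).
#' @export
fit_lda <- function(documents, K, alpha = 50 / K, eta = 0.01, n_restarts = 5,
                    max_iter = 200, tol = 1e-5, seed = 1) {
  stopifnot(K >= 1, length(documents) >= K)
  W <- documents[[1]]$n_words
  if (any(vapply(documents, `[[`, integer(1), "n_words") != W)) {
    stop("documents have inconsistent vocabularies", call. = FALSE)
  }
  fits <- lapply(seq_len(n_restarts), function(r) {
    fit_lda_once(documents, K, alpha, eta, max_iter, tol, seed + r - 1)
  })
  finals <- vapply(fits, function(f) f$bounds[f$iterations], numeric(1))
  best_i <- which.max(finals)
  best <- fits[[best_i]]
  if (!best$converged) {
    warning(sprintf("variational EM did not converge within %d iterations", max_iter),
            call. = FALSE)
  }
  monotone_slack <- if (best$iterations > 1) max(-diff(best$bounds)) else 0
  word_distributions <- best$lambda / rowSums(best$lambda)
  loadings <- best$gamma / rowSums(best$gamma)
  rownames(loadings) <- vapply(documents, function(d) {
    if (is.null(d$subject_id)) NA_character_ else d$subject_id
  }, character(1))
  colnames(loadings) <- sprintf("factor_%d", seq_len(K))
  factors <- new_factor_set(word_distributions)
  metadata <- list(iterations = best$iterations, bound_trace = best$bounds,
                   restart_index = best_i, restart_bounds = finals,
                   converged = best$converged, monotone_violation = monotone_slack,
                   alpha = alpha, eta = eta, seed = seed)
  list(factors = factors, loadings = loadings, metadata = metadata)
}

new_factor_set <- function(word_distributions) {
  K <- nrow(word_distributions)
  W <- ncol(word_distributions)
  E <- W / 2L
  R <- as.integer((1 + sqrt(1 + 8 * E)) / 2)
  stopifnot(n_edges(R) == E)
  fs <- structure(list(K = K, word_distributions = word_distributions,
                       R = R, signed_matrices = NULL),
                  class = "factor_set")
  fs$signed_matrices <- factors_to_matrices(fs)
  fs
}

#' Render factor word distributions as signed matrices
#'
#' For each edge, signed value = P(positive word | k) - P(negative word | k),
#' mirrored into a symmetric matrix with zero diagonal. Positive entries are
#' hyper-connectivity (or hyper-similarity), negative entries hypo-.
#'
#' @param fs A `factor_set`.
#' @return List of K symmetric matrices.
#' @export
factors_to_matrices <- function(fs) {
  wd <- fs$word_distributions
  E <- ncol(wd) / 2L
  lapply(seq_len(fs$K), function(k) {
    signed <- wd[k, seq_len(E)] - wd[k, E + seq_len(E)]
    mirror_lower(signed, fs$R)
  })
}

#' @export
print.factor_set <- function(x, ...) {
  cat(sprintf("<factor_set: K = %d, R = %d regions, %d-word vocabulary>\n",
              x$K, x$R, ncol(x$word_distributions)))
  invisible(x)
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
    }
  }
  out
}

extract_matrices <- function(x) {
  if (inherits(x, "factor_set")) return(x$signed_matrices)
  if (is.list(x)) return(lapply(x, sim_values))
  stop("expected a factor_set or a list of matrices", call. = FALSE)
}

#' Align candidate factors to a reference by permutation
#'
#' Finds the factor permutation maximizing the total lower-triangle Pearson
#' correlation between matched signed matrices (exhaustive search for
#' K <= 8, greedy best-match assignment beyond). Used to resolve label
#' switching when comparing restarts or scoring recovery against ground
#' truth.
#'
#' @param reference,candidate `factor_set`s or lists of symmetric matrices
#'   with equal K and parcellation.
#' @return List with `permutation` (candidate index for each reference
#'   factor), `match_correlations`, and `matched` (candidate matrices
#'   reordered; a reordered `factor_set` if one was supplied).
#' @export
align_factors <- function(reference, candidate) {
  ref_m <- extract_matrices(reference)
  cand_m <- extract_matrices(candidate)
  K <- length(ref_m)
  if (length(cand_m) != K) stop("reference and candidate have different K", call. = FALSE)
  ref_lt <- vapply(ref_m, lower_triangle, numeric(n_edges(nrow(ref_m[[1]]))))
  cand_lt <- vapply(cand_m, lower_triangle, numeric(n_edges(nrow(cand_m[[1]]))))
  if (nrow(ref_lt) != nrow(cand_lt)) stop("parcellations differ", call. = FALSE)
  C <- suppressWarnings(stats::cor(ref_lt, cand_lt))
  C[is.na(C)] <- 0
  if (K <= 8) {
    perms <- all_permutations(K)
    scores <- vapply(perms, function(p) sum(C[cbind(seq_len(K), p)]), numeric(1))
    perm <- perms[[which.max(scores)]]
  } else {
    perm <- integer(K)
    avail <- rep(TRUE, K)
    ord <- order(apply(C, 1, max), decreasing = TRUE)
    for (i in ord) {
      j <- which.max(ifelse(avail, C[i, ], -Inf))
      perm[i] <- j
      avail[j] <- FALSE
    }
  }
  perm <- as.integer(perm)
  matched <- if (inherits(candidate, "factor_set")) {
    new_factor_set(candidate$word_distributions[perm, , drop = FALSE])
  } else {
    cand_m[perm]
  }
  list(permutation = perm,
       match_correlations = C[cbind(seq_len(K), perm)],
       matched = matched)
}
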