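test_that("edge documents follow the two-channel rounding rule", {
  m <- matrix(0, 3, 3)
  m[2, 1] <- m[1, 2] <- 0.23
  m[3, 1] <- m[1, 3] <- -0.26
  doc <- matrix_to_document(m, scale = 10)
  # canonical edge order: (2,1), (3,1), (3,2); vocab: 3 pos then 3 neg words
  expect_identical(doc$ids, c(1L, 5L))
  expect_identical(doc$counts, c(2, 3))
  expect_identical(doc$total, 5)
  # zero edge contributes to neither channel; channels are exclusive
  E <- 3
  pos <- neg <- numeric(E)
  pos[doc$ids[doc$ids <= E]] <- doc$counts[doc$ids <= E]
  neg[doc$ids[doc$ids > E] - E] <- doc$counts[doc$ids > E]
  expect_true(all(pos * neg == 0))

  expect_error(matrix_to_document(matrix(0.001, 3, 3) - diag(3) * 0.001, scale = 10),
               "zero total")
})

test_that("document construction is scale-consistent", {
  fix <- make_small_cohort(N = 30)
  d10 <- build_corpus(fix$matrices, scale = 10)
  d20 <- build_corpus(fix$matrices, scale = 20)
  t10 <- sapply(d10, `[[`, "total")
  t20 <- sapply(d20, `[[`, "total")
  expect_equal(t20 / t10, rep(2, 30), tolerance = 0.05) # doubling up to rounding

  f10 <- fit_lda(d10, 3, n_restarts = 2, seed = 40)
  f20 <- fit_lda(d20, 3, n_restarts = 2, seed = 40)
  al <- align_factors(f10$factors, f20$factors)
  expect_lt(mean(abs(f10$loadings - f20$loadings[, al$permutation])), 0.05)
})

test_that("single-factor corpus yields degenerate simplex loadings", {
  truth <- gen_factor_truth(1, 10, edge_density = 0.5, seed = 41)
  coh <- gen_cohort_matrices(truth, 10, noise_sd = 0.02, seed = 42)
  docs <- build_corpus(coh$matrices)
  fit <- fit_lda(docs, 1, n_restarts = 1, seed = 43)
  expect_equal(unname(fit$loadings), matrix(1, 10, 1))
  expect_equal(unname(rowSums(fit$factors$word_distributions)), 1, tolerance = 1e-10)
})

test_that("fit is deterministic given the seed and tracks a monotone bound", {
  fix <- make_small_cohort(N = 25)
  docs <- build_corpus(fix$matrices)
  f1 <- fit_lda(docs, 3, n_restarts = 2, seed = 44)
  f2 <- fit_lda(docs, 3, n_restarts = 2, seed = 44)
  expect_identical(f1$loadings, f2$loadings)
  expect_identical(f1$factors$word_distributions, f2$factors$word_distributions)
  # ELBO non-decreasing within numerical slack
  expect_lte(f1$metadata$monotone_violation, 1e-6)
  expect_true(all(diff(f1$metadata$bound_trace) > -1e-6))
  # simplex invariants
  expect_equal(unname(rowSums(f1$loadings)), rep(1, 25), tolerance = 1e-10)
  expect_true(all(f1$loadings >= 0))
  expect_equal(unname(rowSums(f1$factors$word_distributions)), rep(1, 3),
               tolerance = 1e-10)
})

test_that("factors are recovered on a small synthetic cohort", {
  fix <- make_small_cohort(K = 3, R = 12, N = 60, seed = 105)
  docs <- build_corpus(fix$matrices)
  fit <- fit_lda(docs, 3, n_restarts = 3, seed = 45)
  al <- align_factors(fix$truth, fit$factors)
  expect_gt(mean(al$match_correlations), 0.8)
  ld <- fit$loadings[, al$permutation]
  subj_cor <- sapply(seq_len(nrow(ld)), function(i) cor(ld[i, ], fix$loadings[i, ]))
  expect_gt(mean(subj_cor), 0.7)
})

test_that("factor alignment resolves label switching", {
  fix <- make_small_cohort(N = 10)
  fs <- fit_lda(build_corpus(fix$matrices), 3, n_restarts = 1, seed = 46)$factors
  # identity
  al <- align_factors(fs, fs)
  expect_identical(al$permutation, 1:3)
  expect_equal(al$match_correlations, rep(1, 3), tolerance = 1e-12)
  # reversal
  rev_fs <- factorscape:::new_factor_set(fs$word_distributions[3:1, ])
  expect_identical(align_factors(fs, rev_fs)$permutation, c(3L, 2L, 1L))
  # unrelated factors match near zero on average
  base <- gen_factor_truth(3, 12, seed = 47)
  mc <- sapply(1:50, function(s) {
    mean(align_factors(base, gen_factor_truth(3, 12, seed = 1000 + s))$match_correlations)
  })
  expect_lt(abs(mean(mc)), 0.25)
  expect_error(align_factors(fs, factorscape:::new_factor_set(fs$word_distributions[1:2, ])),
               "different K")
})

test_that("signed matrices respect the hyper/hypo sign semantics", {
  E <- n <- 6 * 5 / 2
  # all mass on positive channels: nonnegative matrix
  wd <- matrix(0, 1, 2 * E)
  wd[1, 1:E] <- 1 / E
  fs <- factorscape:::new_factor_set(wd)
  expect_true(all(fs$signed_matrices[[1]] >= 0))
  # equal pos/neg mass on an edge cancels
  wd2 <- matrix(0, 1, 2 * E)
  wd2[1, 1] <- wd2[1, E + 1] <- 0.5
  fs2 <- factorscape:::new_factor_set(wd2)
  expect_equal(fs2$signed_matrices[[1]][2, 1], 0)
  # total signed mass bounded by total probability
  fix <- make_small_cohort(N = 10)
  fs3 <- fit_lda(build_corpus(fix$matrices), 3, n_restarts = 1, seed = 48)$factors
  for (k in 1:3) {
    expect_lte(sum(abs(lower_triangle(fs3$signed_matrices[[k]]))), 1 + 1e-12)
  }
})
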