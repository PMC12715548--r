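---
title: "Dimensional subtyping of brain networks with latent connectivity factors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dimensional subtyping of brain networks with latent connectivity factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(factorscape)
```

## The problem

Clinical neuroimaging cohorts — autism spectrum disorder being the motivating
case — are heterogeneous: no single "representative" connectivity pattern
describes every patient. Discrete clustering forces each subject into one
subtype; a dimensional model instead expresses every subject as a mixture of
a few latent factors, with a nonnegative loading vector on the simplex. This
package implements that dimensional-subtyping workflow for two network
modalities:

* **Functional connectivity (FC)** — Pearson correlation between regional
  BOLD time series, a state-like measure.
* **Morphometric similarity (MIND, Morphometric INverse Divergence)** —
  similarity of two cortical regions' multivariate distributions of
  vertex-level anatomical features (thickness, volume, area, curvature,
  sulcal depth), a trait-like measure.

Both produce a symmetric region-by-region matrix per subject; the factor
model, comparison statistics and receptor annotation operate identically on
either.

Real patient MRI is access-restricted, so the package ships a synthetic
cohort generator whose ground truth (factor matrices, subject loadings,
regional Gaussians, receptor fields, behavioral couplings) is known exactly.
Every methodological claim the package makes is validated as a
parameter-recovery experiment against that generator.

## Morphometric similarity

Each region is treated as a cloud of vertices in feature space. Features are
first z-scored across the subject's pooled vertex set — they live on
incommensurate units (mm, mm², dimensionless curvature), and without
standardization a single large-unit feature dominates the divergence.
Standardization is per subject; a cohort-level variant would mix
between-subject differences into within-subject geometry, which is not what
a similarity *within* one brain should reflect.

For a region pair (P, Q) the package computes the symmetrized
Kullback–Leibler divergence

$$D(P, Q) = \tfrac{1}{2}\left[\mathrm{KL}(P\|Q) + \mathrm{KL}(Q\|P)\right],
\qquad \mathrm{MIND}(P, Q) = \frac{1}{1 + D} \in (0, 1],$$

with two estimators:

* `estimator = "gaussian"`: each region is summarized by its sample mean and
  covariance and the closed-form Gaussian KL is used. Exact when the
  generator's regions *are* Gaussian, and the oracle for testing.
* `estimator = "knn"` (default `k = 3`): the nonparametric
  Wang–Kulkarni–Verdú k-nearest-neighbour density-ratio estimate
  $(F/n)\sum_i \ln(\nu_k(i)/\rho_k(i)) + \ln(m/(n-1))$, which makes no
  distributional assumption. Finite-sample estimates can dip slightly below
  zero and are clamped at 0; exact duplicate vertices would produce zero
  neighbour distances and are resolved by substituting the smallest positive
  distance observed times 1e-6, deterministically.

The arithmetic-mean symmetrization keeps `1/(1+D)` interpretable as a
similarity in (0, 1]. A known property of the k-NN estimator is a negative
bias that grows with the true divergence (the low-density tail of Q is
undersampled); at 2000 samples in five dimensions the median error is about
−0.09 at KL = 0.5 but −0.8 at KL = 3. The package therefore treats the
Gaussian path as the quantitative reference and the k-NN path as the
assumption-free cross-check; both recover the *ranking* of true divergences
essentially perfectly (Spearman ρ > 0.99 at 500 vertices/region), which is
what the downstream z-normalization and factorization consume.

With `znorm = TRUE` the off-diagonal similarities are z-scored over the
lower triangle and mirrored back, giving a signed matrix (hyper-/hypo-
similarity); the diagonal is set to the maximum z purely for display and
excluded from every statistic. Z-normalization is within subject by default
(the scope across which a z-score is computed is configurable, as cohort
conventions differ).

## Functional connectivity

`fc_from_timeseries()` is plain Pearson correlation over T×R parcellated
series. Multi-run acquisitions are averaged in Fisher-z space
(`average_runs()`): `atanh` is applied off-diagonal, runs averaged, and the
result kept in z units. The diagonal (r = 1 ↦ ∞) is excluded from the
transform and set to 0 — no downstream statistic uses it, since every
comparison runs on the lower triangle. Off-diagonal correlations within
1e-12 of ±1 arise only from numerically duplicated series; they are clipped
to ±(1 − 1e-7) with a warning rather than propagating infinities. Patient
matrices enter the factorization as raw r, without any reference-group
normalization; a per-edge cohort z-scoring switch exists for parity with
normalized workflows but defaults off.

## The latent factor model

Factorization uses latent Dirichlet allocation on "edge documents". Each
subject's signed matrix is vectorized over the `E = R(R−1)/2` lower-triangle
edges in a fixed canonical order; every edge owns two vocabulary words, a
positive (hyper) and a negative (hypo) channel, and the value x contributes
`round(s·max(x, 0))` and `round(s·max(−x, 0))` counts respectively
(half-away-from-zero rounding, fixed across platforms). The count scale `s`
(default 10) only discretizes: doubling it doubles every count up to
rounding, and fitted loadings shift by well under 0.05 — a property the test
suite asserts.

The model is smoothed LDA: subject-specific factor proportions θ ~
Dirichlet(α), factor word distributions β ~ Dirichlet(η). Inference is
variational EM with coordinate-ascent E-steps and a closed-form M-step; the
evidence lower bound (ELBO) is non-decreasing by construction and its trace
is stored in the fit metadata — any violation beyond 1e-6 fails the test
suite. Defaults follow standard topic-model practice: α = 50/K, η = 0.01,
five random restarts (best final bound wins), convergence at a relative
bound change of 1e-5. K is fixed by configuration (three in the motivating
study); no model selection is attempted. Because α enters the variational
posterior as an additive constant in the Dirichlet parameters, per-subject
loading *correlations* with ground truth are insensitive to its exact value.

Factors are rendered as signed matrices, P(pos word) − P(neg word) per edge,
and label switching is resolved by `align_factors()` — exhaustive
permutation search maximizing summed lower-triangle correlation (K ≤ 8; a
greedy assignment beyond, far past any realistic K here).

Under the generator's conditions (K = 3, N = 100, R = 20, Dirichlet α = 0.5,
edge noise 0.05) recovery is essentially exact: mean factor correlation and
mean per-subject loading correlation both ≈ 0.99.

## Comparison statistics

Factor correspondence (patient factors vs a control group-average pattern,
or structure vs function) is the Pearson correlation of vectorized lower
triangles. Behavior associations are pairwise-complete Pearson correlations
of loadings with scale scores, two-sided t-test p-values, no multiplicity
correction by default (cells with fewer than three complete pairs are
flagged, not computed). These choices deliberately mirror common reporting
practice in the subtyping literature.

For receptor annotation each factor matrix is reduced to one value per
region: the first principal component of the R×R matrix treated as R
observations over R variables (column-centered), sign-fixed to correlate
nonnegatively with the row means. The alternative — PCA in edge space — does
not yield a region vector and cannot be matched to region-wise receptor
maps, which is why the regions-as-rows orientation is used. That summary is
then regressed on all 19 standardized receptor density maps jointly
(response standardized, so coefficients are standardized betas); reading the
per-transmitter weights from a single joint model matches reporting a
weight for each transmitter from one regression per factor. A
one-map-at-a-time variant is available behind `method = "simple"`.

## The spin permutation null

Cortical maps are spatially autocorrelated, so parametric regression
p-values are anticonservative. Significance is therefore assessed against a
spin null: each permutation draws a uniform random 3-D rotation, applies it
to the left hemisphere's sphere and the mirrored rotation to the right, and
reassigns rotated parcels to original parcels by greedy unique
nearest-neighbour matching — producing a true within-hemisphere permutation
that preserves each map's value multiset and (approximately) its spatial
autocorrelation. The permutation is applied to the response vector rather
than to all 19 predictor maps; under a rigid rotation of a common
coordinate frame the two are equivalent, and permuting the response costs
one matrix multiply per spin. Empirical p-values use the add-one rule,
`p = (1 + #{|β_perm| ≥ |β_obs|})/(n_perm + 1)`, two-sided, with
Benjamini–Hochberg q-values reported alongside (the motivating literature
reports uncorrected spin p-values; providing both is conservative). The
default is 1000 spins; calibration experiments in this package use 500.

Two geometric modeling choices matter and were made a priori:

* **Each hemisphere is its own full sphere**, as in surface-based
  registration. Placing two hemispheres on one shared sphere makes rotations
  carry parcels off-hemisphere and reduces spins to near-random
  permutations.
* **Parcel centroids form a quasi-uniform (Fibonacci) lattice**, randomly
  oriented per hemisphere. Real parcellations tile the surface with roughly
  equal-area parcels; with quasi-uniform spacing the rotated point set
  overlays the original grid and greedy reassignment displaces parcels by
  less than one parcel spacing on average, so spun maps retain > 90% of
  their nearest-neighbour autocorrelation. (With Poisson-random centroids
  even optimal assignment loses ~25%.)

Under these conditions the test is well calibrated: with a response field
generated independently of the maps, the per-transmitter rejection rate at
α = 0.05, pooled over 19 transmitters and 200 datasets at R = 400, falls
inside the exact binomial 95% interval around 0.05; a response equal to one
map plus small noise drives that transmitter's p to the permutation floor.

## The synthetic cohort generator

The generator emulates the statistical structure of a dimensional-subtyping
study, not MRI physics:

* **Factor matrices**: K symmetric signed matrices, ~25% edge density with
  supports drawn to lean disjoint, and rejection sampling enforcing pairwise
  lower-triangle |r| < 0.5 — identifiable ground truth for recovery tests.
* **Subjects**: matrix = Σₖ loadingₖ·factorₖ + symmetric Gaussian edge noise
  (sd 0.05 by default), loadings ~ Dirichlet(0.5) — sparse-leaning mixtures
  typical of dimensional subtyping plots. The linear-mixture form is an
  assumption made for testability; it is the simplest generative model under
  which loadings are identifiable, not a claim about patient biology.
* **Vertex clouds**: region Gaussians with means of sd = `separation` and
  covariances interpolating identity with a random SPD matrix; `separation
  = 0` collapses all regions onto one distribution (all divergences zero).
* **Time series**: exact multivariate Gaussian draws from a target
  correlation matrix (eigen square root), so sample FC converges to the
  target at rate 1/√T.
* **Receptor maps**: k-nearest-neighbour graph smoothing (k = 6, 2 rounds
  by default) of white noise on the hemisphere spheres, standardized per
  map; `smoothness = 0` gives spatially unstructured maps for null
  experiments.
* **Behavior**: scores = loadings × effects + Gaussian noise. The default
  study couples SCQ and SRS to morphometric loadings at population r ≈ 0.3
  and leaves every functional-side association an exact null, echoing the
  qualitative dissociation the motivating study reports (effect sizes of
  that order are what its printed correlations, ~0.16–0.31, suggest).

What passing these tests does **not** show: robustness to site effects,
motion artifacts, non-Gaussian vertex distributions, model misspecification
(subjects that are not linear factor mixtures), or K chosen wrongly. The
generator is a statistical emulator; conclusions about real cohorts require
the real preprocessing chain upstream.

## Problem sizes and numerical choices

The shipped experiments use deliberately small cohorts chosen as the
smallest sizes at which each property is comfortably identifiable: R = 20
regions and N = 60–150 subjects for factorization experiments (the demo
completes in seconds), 500 vertices/region for divergence recovery,
R = 400 — the motivating study's parcellation size — for spin-test
calibration. Document counts use scale 10; EM runs at tol 1e-5 with 3–5
restarts. Degenerate inputs error early and by name: zero-variance features
or regions, non-PSD correlation targets (the offending eigenvalue is
printed), collinear receptor maps (condition number > 1e8, offending pairs
listed), all-zero edge documents (suggesting a larger count scale).

`run_full_pipeline()` chains simulate → MIND + FC → factorize → compare →
behavior → receptors, writes every table as delimited text with JSON
sidecars, serializes its exact configuration and an md5 manifest into the
output directory, and is bit-reproducible for a fixed master seed
(single-threaded, fixed reduction order; every stage seed is a fixed offset
of the master). `validate_inputs()` re-reads a bundle and reports symmetry,
label-agreement and simplex violations machine-readably. The
`analysis/01…04` scripts present the same workflow as a narrated sequence.

## Known limitations

* The k-NN divergence estimator's bias at large divergences (see above)
  makes raw MIND values estimator-dependent; rankings, and hence z-normed
  MIND, are stable.
* Spin nulls are approximate: ~7% of lag-1 autocorrelation is lost to
  reassignment even on the lattice geometry, and calibration was verified
  at the default smoothness — much rougher or much smoother fields deserve
  a fresh calibration check.
* The LDA edge-document construction inherits an arbitrary count scale; only
  scale-robust conclusions (recovery, loadings to within 0.05) should be
  drawn.
* Group-average patterns stand in for a control-group "factor"; the package
  does not implement reference-normalized factorization beyond the optional
  per-edge centering switch.
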