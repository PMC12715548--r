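# factorscape

Dimensional subtyping of brain networks by latent connectivity factors.

Clinical neuroimaging cohorts are heterogeneous: rather than sorting
subjects into discrete clusters, a dimensional model represents every
subject as a mixture of a few latent connectivity patterns. `factorscape`
implements that workflow end to end for two modalities —

* **MIND** (Morphometric INverse Divergence): similarity of two cortical
  regions' multivariate vertex-feature distributions,
  `MIND = 1/(1 + D)` with `D` the symmetrized Kullback–Leibler divergence,
  estimated in closed form under a Gaussian model or nonparametrically by
  k-nearest-neighbour density ratios;
* **FC** (functional connectivity): Pearson correlation between regional
  BOLD time series, with Fisher r-to-z multi-run averaging —

and decomposes a cohort of signed matrices into K latent factors with
per-subject simplex loadings via smoothed latent Dirichlet allocation
(variational EM on two-channel hyper/hypo edge documents). Factors are then
characterized by lower-triangle correspondence statistics, loading–behavior
correlations, and regression on 19 neurotransmitter receptor density maps
tested against a spin-permutation spatial null.

Real patient MRI is access-restricted, so the package includes a synthetic
cohort generator with exact ground truth (factor matrices, Dirichlet
loadings, regional Gaussians, autocorrelated receptor fields, behavior
couplings); every methodological guarantee is validated as a
parameter-recovery experiment against it. The model, estimators, defaults
and design decisions are documented in
`vignettes/dimensional-subtyping.Rmd`.

## Worked example

The demo runs the full pipeline on a synthetic cohort (20 regions, 60
patients, 30 controls, 3 factors per modality) in a few seconds:

```r
library(factorscape)
res <- run_demo_pipeline("demo_out", seed = 7)
#> [simulate] 0.1s R=20 N=60 K=3
#> [mind] 0.1s recovery rho=0.958
#> [fc] 0.2s 60 subject FC matrices
#> [factorize_mind] 2.6s mean truth r=0.998
#> [factorize_fc] 6.5s mean truth r=0.972
#> [compare] 6.5s
#> [behavior] 6.5s
#> [receptors] 6.6s 500 spins
nrow(validate_inputs("demo_out"))   # 0 — bundle is consistent
```

Reading the log: the MIND stage re-estimated a similarity matrix from
generated vertex clouds and ranked the true region divergences at Spearman
ρ = 0.958; the two LDA fits recovered the generating factor matrices at
mean lower-triangle correlation 0.998 (MIND) and 0.972 (FC). `demo_out/`
then contains, as delimited text with JSON sidecars: per-subject matrices,
fitted signed factor matrices and simplex loadings per modality,
factor-vs-control-average and structure–function correspondence tables,
loading–behavior correlations (the generator couples behavior to the
morphometric side only), and per-transmitter receptor betas with spin
p-values, plus the exact config and an md5 manifest. Rerunning with the
same seed reproduces every file bit for bit.

The same workflow, presented as a narrated analysis at a larger cohort size
(N = 120), lives in `analysis/01_simulate_cohort.R` through
`analysis/04_factor_characterization.R`; each stage prints what it found
and writes its tables under `results/`, e.g.

```
MIND: 40 EM iterations (restart 1 of 3), truth alignment r = 0.999/0.999/0.998
Cells with p < .005: 2 (modalities: mind) - the dissociation pattern.
```

— the behavioral association shows up on the morphometric side and nowhere
on the functional side, the qualitative signature the dimensional-subtyping
design is built to detect.

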