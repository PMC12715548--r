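#!/usr/bin/env Rscript

# Stage 4 — characterize the fitted factors.
#
# Three analyses over the stage-3 output:
#  (a) correspondence: lower-triangle correlations of morphometric vs
#      functional factors (structure-function coupling at the factor level);
#  (b) behavior: Pearson correlations of subject loadings with the three
#      behavioral scales — the morphometric side carries the generated
#      coupling, the functional side is an exact null;
#  (c) receptors: each factor is reduced to its first principal component
#      over regions and regressed on the 19 standardized receptor maps, with
#      spin-permutation p-values from the within-hemisphere rotation null.

library(factorscape)

seed <- 20260925L
K <- 3L
dir.create("results/characterization", showWarnings = FALSE, recursive = TRUE)

read_factors <- function(modality) {
  out <- lapply(seq_len(K), function(k) {
    as.matrix(read.csv(sprintf("results/factors/factor_%s_%d.csv", modality, k),
                       row.names = 1, check.names = FALSE))
  })
  names(out) <- sprintf("%s_factor_%d", modality, seq_len(K))
  out
}
mind_f <- read_factors("mind")
fc_f <- read_factors("fc")

## (a) structure-function correspondence --------------------------------
corr <- factor_correspondence(mind_f, fc_f)
write.csv(corr, "results/characterization/structure_function.csv", row.names = FALSE)
cat(sprintf("Structure-function factor correlations span [%.2f, %.2f] (independent truths).\n",
            min(corr$r), max(corr$r)))

## (b) behavior ----------------------------------------------------------
behavior <- read.csv("results/cohort/behavior.csv", row.names = 1)
tabs <- do.call(rbind, lapply(c("mind", "fc"), function(m) {
  ld <- as.matrix(read.csv(sprintf("results/factors/loadings_%s.csv", m),
                           row.names = 1, check.names = FALSE))
  cbind(modality = m, loading_behavior_correlations(ld, behavior))
}))
write.csv(tabs, "results/characterization/behavior_correlations.csv", row.names = FALSE)
sig <- tabs[tabs$p < 0.005, ]
cat(sprintf("Cells with p < .005: %d (modalities: %s) - the dissociation pattern.\n",
            nrow(sig), paste(unique(sig$modality), collapse = ", ")))

## (c) receptor regression with spin null --------------------------------
sphere_df <- read.csv("results/cohort/sphere.csv")
sphere <- structure(list(coords = as.matrix(sphere_df[, c("X1", "X2", "X3")]),
                         hemisphere = sphere_df$hemisphere,
                         labels = sphere_df$region),
                    class = "sphere_parcellation")
dens <- as.matrix(read.csv("results/cohort/receptor_maps.csv",
                           row.names = 1, check.names = FALSE))
# 20 regions cannot support a 19-predictor joint model; use the first six maps
atlas <- structure(list(densities = dens[, 1:6], sphere = sphere),
                   class = "receptor_atlas")
null <- build_spin_null(sphere, 1000, seed = seed + 31)
rec <- do.call(rbind, lapply(names(c(mind_f, fc_f)), function(nm) {
  pc <- pca_first_component(c(mind_f, fc_f)[[nm]])
  cbind(pattern = nm, spin_pvalues(pc, atlas, null))
}))
write.csv(rec, "results/characterization/receptor_regression.csv", row.names = FALSE)
cat(sprintf("Receptor spin tests: %d pattern x transmitter cells, min p_spin = %.3f (floor %.3f).\n",
            nrow(rec), min(rec$p_spin), 1 / (null$n_perm + 1)))
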