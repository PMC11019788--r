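#!/usr/bin/env Rscript
## Stage 1: simulate the study cohort.
##
## Builds the default generator truth -- the 29 reference species with their
## published per-age-group prevalence/abundance, geography-marker species,
## group richness targets 42/84/83/86 and the censored log-normal read-depth
## model -- and draws 250 samples per WHO age group (a desk-scale stand-in
## for the 6,653-sample pooled cohort). Outputs go to results/cohort/.

library(agecore)

seed <- 1L
cfg <- default_synthetic_config(n_per_group = c(G1 = 250, G2 = 250,
                                                G3 = 250, G4 = 250))
cohort <- generate_cohort(cfg, seed = seed)
write_cohort(cohort, "results/cohort")

cat("samples:", ncol(cohort$counts),
    "| taxa:", nrow(cohort$counts),
    "| EC reactions:", nrow(cohort$ec), "\n")
cat("samples per group:\n")
print(table(cohort$metadata$age_group))
cat("mean classified reads per sample:",
    round(mean(colSums(cohort$counts))), "\n")
cat("written to results/cohort/\n")
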