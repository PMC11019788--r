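#!/usr/bin/env Rscript
## Stage 6: continent-of-origin associations.
##
## MaAsLin2-style multivariable model per age group (TSS, log2 with
## half-minimum pseudocount, linear model, Europe as reference, BH within age
## group), then the cross-age-group consistency filter.

library(agecore)

dat <- load_profile_table("results/cohort/profile.tsv",
                          "results/cohort/metadata.tsv")
rel <- to_relative(subsample_reads(dat$counts, cap = 100000, seed = 2L))

## drop pool-filler taxa from reporting; keep configured species
feats <- rel[!grepl("^synthetic_filler", rownames(rel)), , drop = FALSE]
assoc <- geo_associate(feats, dat$metadata, alpha = 0.05)
write.table(assoc, "results/geography.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("fitted contrasts:", nrow(assoc),
    "| significant (q<0.05):", sum(assoc$significant), "\n")
cat("significant contrasts by continent:\n")
print(table(assoc$contrast[assoc$significant]))

cons <- consistency_filter(assoc)
write.table(cons, "results/geography_consistent.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
flagged <- cons[cons$consistent, ]
cat("consistent across age groups:", nrow(flagged), "feature-contrasts\n")
print(flagged[, c("feature", "contrast", "sign", "n_groups")],
      row.names = FALSE)
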