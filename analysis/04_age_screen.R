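#!/usr/bin/env Rscript
## Stage 4: two-stage age-association screen.
##
## Stage 1: Spearman correlation of each taxon with age (p < 0.01, BH q
## reported). Stage 2: one-way ANOVA + Tukey HSD (p < 0.05) requiring
## enrichment in at least one age group. Selected taxa are partitioned by
## correlation sign.

library(agecore)

dat <- load_profile_table("results/cohort/profile.tsv",
                          "results/cohort/metadata.tsv")
rel <- to_relative(subsample_reads(dat$counts, cap = 100000, seed = 2L))

s1 <- spearman_age_screen(rel, dat$metadata, alpha = 0.01)
s2 <- anova_tukey_filter(rel, dat$metadata, alpha = 0.05)
sel <- select_age_associated(s1, s2)
write.table(sel$results, "results/age_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("taxa tested:", nrow(sel$results),
    "| stage-1 pass (p<0.01):", sum(sel$results$pass_stage1),
    "| selected:", sum(sel$results$selected), "\n")
cat("negative with age:", length(sel$negative_with_age), "taxa\n")
print(utils::head(sel$negative_with_age, 10))
cat("positive with age:", length(sel$positive_with_age), "taxa\n")
cat("strongest negative correlations:\n")
print(utils::head(sel$results[sel$results$selected,
                              c("taxon", "rho", "p_value", "q_value")], 5),
      row.names = FALSE)
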