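#!/usr/bin/env Rscript
## Stage 2: intra- and inter-individual diversity.
##
## Applies the 100,000-read shallow-shotgun cap, then: species richness and
## Shannon index per sample with pairwise Kruskal-Wallis compact letters
## across age groups; Bray-Curtis dissimilarities, PCoA, global and pairwise
## PERMANOVA (999 permutations), and envfit-style fitting of age onto the
## ordination.

library(agecore)

dat <- load_profile_table("results/cohort/profile.tsv",
                          "results/cohort/metadata.tsv")
counts <- subsample_reads(dat$counts, cap = 100000, seed = 2L)
rel <- to_relative(counts)
meta <- dat$metadata

alpha <- data.frame(sample = colnames(counts),
                    age_group = meta$age_group,
                    richness = richness(counts),
                    shannon = shannon(rel + 0))
write.table(alpha, "results/diversity_alpha.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("mean richness by age group:\n")
print(round(tapply(alpha$richness, alpha$age_group, mean), 1))
cld <- pairwise_kruskal(alpha$richness, alpha$age_group, alpha = 0.05)
cat("richness letters:", paste(names(cld$letters), cld$letters,
                               sep = "=", collapse = " "), "\n")
cld_s <- pairwise_kruskal(alpha$shannon, alpha$age_group, alpha = 0.05)
cat("Shannon letters: ", paste(names(cld_s$letters), cld_s$letters,
                               sep = "=", collapse = " "), "\n")

D <- bray_curtis(rel)
ord <- agecore::pcoa(D, k = 2)
cat("PCoA axis variance explained:",
    paste(round(100 * ord$proportion_explained, 1), collapse = "% / "),
    "%\n")

glob <- permanova(D, meta$age_group, n_perm = 999, seed = 3L)
cat(sprintf("global PERMANOVA: pseudo-F = %.2f, R2 = %.3f, p = %.3f\n",
            glob$pseudo_F, glob$R2, glob$p_value))
pw <- pairwise_permanova(D, meta$age_group, n_perm = 999, seed = 3L)
write.table(pw, "results/diversity_pairwise_permanova.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("pairwise PERMANOVA (q < 0.01):",
    sum(pw$q_value < 0.01), "of", nrow(pw), "pairs\n")

fit <- envfit_ord(ord, data.frame(age_years = meta$age_years),
                  n_perm = 999, seed = 4L)
write.table(fit, "results/diversity_envfit.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("age fit on ordination: r2 = %.3f, p = %.3f\n",
            fit$r_squared, fit$p_value))
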