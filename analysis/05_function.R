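#!/usr/bin/env Rscript
## Stage 5: functional (EC reaction) layer.
##
## Correlates the age-associated taxa with the key-enzyme reaction abundances
## (beta-galactosidase, thiamine/niacin biosynthesis, fiber, carbohydrate,
## SCFA enzymes), then summarises mean signed correlations per age group's
## core/accessory taxa and enzyme category.

library(agecore)

dat <- load_profile_table("results/cohort/profile.tsv",
                          "results/cohort/metadata.tsv")
ec <- read_ec_table("results/cohort/ec.tsv")
rel <- to_relative(subsample_reads(dat$counts, cap = 100000, seed = 2L))

screen <- read.delim("results/age_screen.tsv")
sel_taxa <- screen$taxon[screen$selected]
cat("age-associated taxa carried into the functional screen:",
    length(sel_taxa), "\n")

corr <- species_ec_correlation(rel[sel_taxa, , drop = FALSE], ec,
                               alpha = 0.05)
write.table(as.data.frame(corr), "results/function_correlations.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("significant species-EC cells:", sum(corr$significant), "of",
    nrow(corr), "\n")

cls <- read.delim("results/core_classification.tsv")
sm <- group_enzyme_summary(corr, cls)
write.table(sm, "results/function_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("mean signed correlation, G1 vs G3 (selected categories):\n")
show <- sm[sm$category %in% c("lactose/HMO", "vitamin-thiamine",
                              "vitamin-niacin", "fiber") &
             sm$group %in% c("G1", "G3"), ]
print(show[order(show$category, show$group), ], row.names = FALSE)
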