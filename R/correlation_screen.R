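#' Stage 1: per-taxon Spearman correlation with age
#'
#' Spearman's rank correlation (average ranks for ties, asymptotic t
#' approximation for the p-value, as `cor.test(exact = FALSE)`) between each
#' taxon's relative abundance and age in years, with Benjamini-Hochberg
#' q-values over all tested taxa. Stage-1 pass is `p < alpha` on the raw
#' p-value (q reported alongside).
#'
#' @param rel Relative-abundance matrix (taxa x samples).
#' @param metadata Metadata aligned to `colnames(rel)` with `age_years`.
#' @param alpha Stage-1 threshold on the raw p-value (default 0.01).
#' @return data.frame: `taxon`, `rho`, `p_value`, `q_value`, `pass_stage1`,
#'   `sign`; taxa absent from every sample are skipped and listed in the
#'   `skipped_taxa` attribute.
#' @export
spearman_age_screen <- function(rel, metadata, alpha = 0.01) {
  assert_count_matrix(rel, "relative-abundance table")
  age <- metadata$age_years[match(colnames(rel), metadata$sample)]
  if (anyNA(age) || length(age) < 3L) {
    stop_agecore(">= 3 samples with ages required",
                 class = "agecore_parameter_error")
  }
  present <- rowSums(rel > 0) > 0
  skipped <- rownames(rel)[!present]
  sub <- rel[present, , drop = FALSE]
  res <- lapply(rownames(sub), function(tx) {
    ct <- suppressWarnings(
      stats::cor.test(sub[tx, ], age, method = "spearman", exact = FALSE)
    )
    data.frame(taxon = tx, rho = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out$pass_stage1 <- !is.na(out$p_value) & out$p_value < alpha
  out$sign <- ifelse(out$rho > 0, "positive",
                     ifelse(out$rho < 0, "negative", "zero"))
  rownames(out) <- NULL
  attr(out, "skipped_taxa") <- skipped
  out
}

#' Stage 2: ANOVA + Tukey HSD group-enrichment filter
#'
#' One-way ANOVA of relative abundance across the four age groups followed by
#' Tukey's honestly-significant-difference test (pooled mean squared error,
#' studentized range distribution). A group is flagged for a taxon when its
#' mean relative abundance significantly exceeds at least one other group's
#' (Tukey `p < alpha`).
#'
#' @inheritParams spearman_age_screen
#' @param alpha Tukey significance level (default 0.05).
#' @param transform Optional variance-stabilising transform of the abundances:
#'   `"none"` (default) or `"asin_sqrt"`.
#' @return data.frame: `taxon`, `anova_p`, one logical `flag_<group>` column
#'   per age group, `any_flag`.
#' @export
anova_tukey_filter <- function(rel, metadata, alpha = 0.05,
                               transform = c("none", "asin_sqrt")) {
  transform <- match.arg(transform)
  assert_count_matrix(rel, "relative-abundance table")
  grp <- metadata$age_group[match(colnames(rel), metadata$sample)]
  lev <- AGE_GROUPS[AGE_GROUPS %in% grp]
  if (any(table(grp)[lev] < 2L) || length(lev) < 2L) {
    stop_agecore("every age group needs >= 2 samples",
                 class = "agecore_parameter_error")
  }
  fgrp <- factor(grp, levels = lev)
  res <- lapply(rownames(rel), function(tx) {
    y <- rel[tx, ]
    if (transform == "asin_sqrt") y <- asin(sqrt(pmin(y, 1)))
    row <- data.frame(taxon = tx, anova_p = NA_real_,
                      stringsAsFactors = FALSE)
    for (g in lev) row[[paste0("flag_", g)]] <- FALSE
    if (stats::var(y) < 1e-300) {
      return(row)   # no variance anywhere: nothing to test for this taxon
    }
    fit <- stats::aov(y ~ fgrp)
    row$anova_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    tk <- stats::TukeyHSD(fit)$fgrp
    for (r in rownames(tk)) {
      gg <- strsplit(r, "-", fixed = TRUE)[[1L]]   # "B-A": diff = mean(B)-mean(A)
      if (tk[r, "p adj"] < alpha) {
        winner <- if (tk[r, "diff"] > 0) gg[1L] else gg[2L]
        row[[paste0("flag_", winner)]] <- TRUE
      }
    }
    row
  })
  out <- do.call(rbind, res)
  flags <- out[, grep("^flag_", names(out)), drop = FALSE]
  if (all(is.na(out$anova_p))) {
    stop_agecore("zero within-group variance for every taxon",
                 class = "agecore_degenerate_error")
  }
  out$any_flag <- rowSums(as.matrix(flags)) > 0
  rownames(out) <- NULL
  out
}

#' Combine the two screening stages and partition by correlation sign
#'
#' A taxon is selected when it passes stage 1 (significant Spearman
#' correlation with age) AND is flagged by stage 2 (significantly enriched in
#' at least one age group). Selected taxa are partitioned by the sign of their
#' correlation and sorted by `rho`.
#'
#' @param stage1 Output of [spearman_age_screen()].
#' @param stage2 Output of [anova_tukey_filter()].
#' @return List of class `agecore_age_screen`: `results` (merged data.frame
#'   with `selected`), `negative_with_age`, `positive_with_age` (character
#'   vectors sorted by increasing rho).
#' @export
select_age_associated <- function(stage1, stage2) {
  m <- merge(stage1, stage2, by = "taxon", all.x = TRUE, sort = FALSE)
  m$any_flag[is.na(m$any_flag)] <- FALSE
  m$selected <- m$pass_stage1 & m$any_flag
  m <- m[order(m$rho), ]
  rownames(m) <- NULL
  structure(list(
    results = m,
    negative_with_age = m$taxon[m$selected & m$rho < 0],
    positive_with_age = m$taxon[m$selected & m$rho > 0]
  ), class = "agecore_age_screen")
}
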