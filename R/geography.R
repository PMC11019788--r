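#' Multivariable continent association (MaAsLin2-style)
#'
#' Per age group and feature: total-sum-scaled abundances are log2-transformed
#' after adding half the feature's minimum positive value as pseudocount, then
#' regressed on continent indicator contrasts with Europe (the reference
#' population) as baseline. P-values per (feature, contrast) are
#' BH-adjusted within each age group.
#'
#' @param features Feature x sample matrix (taxa relative abundances or EC
#'   reaction abundances; columns are total-sum scaled internally).
#' @param metadata Metadata aligned to `colnames(features)` with `age_group`
#'   and `continent`.
#' @param alpha Significance level on the q-value (default 0.05).
#' @param reference Reference continent (default `"Europe"`).
#' @param min_n Minimum samples per (group, continent) cell for the contrast
#'   to be fitted (default 5).
#' @param groups Age groups analysed (defaults to those present).
#' @return data.frame: `feature`, `age_group`, `contrast`, `coefficient`,
#'   `p_value`, `q_value`, `significant`. Empty (with a warning) when only the
#'   reference continent is present.
#' @export
geo_associate <- function(features, metadata, alpha = 0.05,
                          reference = "Europe", min_n = 5L,
                          groups = NULL) {
  assert_count_matrix(features, "feature table")
  meta <- metadata[match(colnames(features), metadata$sample), ]
  if (is.null(groups)) groups <- intersect(AGE_GROUPS, unique(meta$age_group))
  empty_result <- data.frame(feature = character(), age_group = character(),
                             contrast = character(), coefficient = numeric(),
                             p_value = numeric(), q_value = numeric(),
                             significant = logical(),
                             stringsAsFactors = FALSE)
  if (length(setdiff(unique(meta$continent), reference)) == 0L) {
    warning("only the reference continent present; nothing to contrast")
    return(empty_result)
  }
  ## TSS normalisation
  tss <- sweep(features, 2L, pmax(colSums(features), 1e-300), "/")
  out <- list()
  for (g in groups) {
    sel <- which(meta$age_group == g & !is.na(meta$continent))
    if (!length(sel)) next
    cont <- meta$continent[sel]
    if (!reference %in% cont) {
      stop_agecore("no ", reference, " samples in group ", g,
                   class = "agecore_reference_error")
    }
    tab <- table(cont)
    keep_cont <- names(tab)[tab >= min_n]
    if (!reference %in% keep_cont || length(keep_cont) < 2L) next
    sel <- sel[cont %in% keep_cont]
    cont <- factor(meta$continent[sel],
                   levels = c(reference, setdiff(keep_cont, reference)))
    sub <- tss[, sel, drop = FALSE]
    rows <- lapply(rownames(sub), function(ft) {
      y <- sub[ft, ]
      pos <- y[y > 0]
      if (!length(pos)) return(NULL)      # feature absent in this group
      pseudo <- min(pos) / 2
      ly <- log2(y + pseudo)
      if (stats::var(ly) < 1e-300) return(NULL)
      fit <- stats::lm(ly ~ cont)
      cf <- summary(fit)$coefficients
      idx <- grep("^cont", rownames(cf))
      data.frame(feature = ft, age_group = g,
                 contrast = sub("^cont", "", rownames(cf)[idx]),
                 coefficient = cf[idx, "Estimate"],
                 p_value = cf[idx, "Pr(>|t|)"],
                 stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, rows)
    if (is.null(block)) next
    block$q_value <- bh_adjust(block$p_value)
    out[[g]] <- block
  }
  if (!length(out)) return(empty_result)
  res <- do.call(rbind, out)
  res$significant <- res$q_value < alpha
  rownames(res) <- NULL
  res
}

#' Cross-age-group consistency filter
#'
#' Keeps (feature, contrast) pairs that are significant with the same
#' coefficient sign in every age group in which the contrast was fitted
#' (requiring at least `min_groups` groups).
#'
#' @param associations Output of [geo_associate()].
#' @param min_groups Minimum number of age groups the contrast must span
#'   (default 2).
#' @return data.frame: `feature`, `contrast`, `sign`, `n_groups`,
#'   `consistent` (the flagged subset has `consistent = TRUE`).
#' @export
consistency_filter <- function(associations, min_groups = 2L) {
  if (!nrow(associations)) {
    return(data.frame(feature = character(), contrast = character(),
                      sign = character(), n_groups = integer(),
                      consistent = logical(), stringsAsFactors = FALSE))
  }
  key <- interaction(associations$feature, associations$contrast, drop = TRUE)
  rows <- lapply(split(associations, key), function(d) {
    n <- length(unique(d$age_group))
    all_sig <- all(d$significant)
    same_sign <- length(unique(sign(d$coefficient))) == 1L
    data.frame(feature = d$feature[1L], contrast = d$contrast[1L],
               sign = if (same_sign && sign(d$coefficient[1L]) > 0) "positive"
                      else if (same_sign) "negative" else "mixed",
               n_groups = n,
               consistent = all_sig && same_sign && n >= min_groups,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
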