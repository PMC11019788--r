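#' Read an aligned taxonomic profile and its sample metadata
#'
#' Loads a species-level classified-read count table (taxa x samples TSV;
#' first column taxon label, header row of sample ids, `#` lines ignored)
#' together with a metadata table (columns `sample`, `age_years` and
#' optionally `continent`, `cohort`). The two files must describe exactly the
#' same samples; WHO age groups and early-life subgroups are derived from
#' `age_years`.
#'
#' @param path Path to the profile TSV (integer read counts).
#' @param metadata_path Path to the metadata TSV.
#' @return A list with elements `counts` (integer matrix, taxa x samples) and
#'   `metadata` (data.frame with `sample`, `age_years`, `continent`, `cohort`,
#'   `age_group`, `age_subgroup`), metadata rows ordered as the count columns.
#' @export
load_profile_table <- function(path, metadata_path) {
  counts <- read_profile_tsv(path)
  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!all(c("sample", "age_years") %in% names(meta))) {
    stop_agecore("metadata requires columns 'sample' and 'age_years'",
                 class = "agecore_format_error")
  }
  meta$sample <- as.character(meta$sample)
  if (anyDuplicated(meta$sample)) {
    stop_agecore("duplicate sample ids in metadata",
                 class = "agecore_alignment_error")
  }
  if (!is.numeric(meta$age_years) || anyNA(meta$age_years) ||
      any(meta$age_years < 0)) {
    stop_agecore("age_years must be non-negative and complete",
                 class = "agecore_format_error")
  }
  only_profile <- setdiff(colnames(counts), meta$sample)
  only_meta <- setdiff(meta$sample, colnames(counts))
  if (length(only_profile) || length(only_meta)) {
    stop_agecore("samples present in only one file: ",
                 paste(c(only_profile, only_meta), collapse = ", "),
                 class = "agecore_alignment_error")
  }
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  rownames(meta) <- NULL
  if (is.null(meta$continent)) meta$continent <- NA_character_
  if (is.null(meta$cohort)) meta$cohort <- NA_character_
  meta$age_group <- assign_age_group(meta$age_years)
  meta$age_subgroup <- assign_age_subgroup(meta$age_years)
  list(counts = counts, metadata = meta)
}

read_profile_tsv <- function(path) {
  if (!file.exists(path)) {
    stop_agecore("file not found: ", path, class = "agecore_format_error")
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop_agecore("profile table needs a taxon column plus >=1 sample column",
                 class = "agecore_format_error")
  }
  taxa <- as.character(df[[1L]])
  if (anyDuplicated(taxa)) {
    stop_agecore("duplicate taxon row labels in ", path,
                 class = "agecore_format_error")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    stop_agecore("non-numeric counts in ", path,
                 class = "agecore_format_error")
  }
  storage.mode(m) <- "double"
  rownames(m) <- taxa
  assert_integer_counts(m, paste0("profile table '", path, "'"))
  storage.mode(m) <- "integer"
  m
}

#' Write a profile (or relative-abundance) table as TSV
#'
#' Mirrors the input layout: first column `taxon`, one column per sample.
#' @param table Numeric matrix with taxon rownames and sample colnames.
#' @param path Output path.
#' @export
write_profile_table <- function(table, path) {
  assert_count_matrix(table, "table")
  df <- data.frame(taxon = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cap each sample at a fixed number of classified reads
#'
#' Implements the shallow-shotgun protocol: every sample whose classified-read
#' total exceeds `cap` is reduced to exactly `cap` reads by uniform sampling
#' without replacement over its reads (a multivariate hypergeometric draw on
#' the taxon counts); samples at or under the cap are left untouched.
#'
#' @param counts Integer matrix, taxa x samples.
#' @param cap Maximum reads retained per sample (default 100000).
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @return Integer matrix of the same shape with column sums `<= cap`.
#' @export
subsample_reads <- function(counts, cap = 100000L, seed = 1L) {
  assert_integer_counts(counts)
  if (length(cap) != 1L || !is.finite(cap) || cap < 1) {
    stop_agecore("cap must be a single integer >= 1",
                 class = "agecore_parameter_error")
  }
  cap <- as.integer(round(cap))
  out <- counts
  with_seed(seed, {
    for (j in seq_len(ncol(counts))) {
      total <- sum(counts[, j])
      if (total > cap) out[, j] <- rmv_hyper(counts[, j], cap)
    }
  })
  storage.mode(out) <- "integer"
  out
}

## Sequential multivariate hypergeometric draw: taxon i keeps
## X_i ~ Hypergeom(n = cap remaining, urn split count_i vs rest).
rmv_hyper <- function(counts, k) {
  out <- integer(length(counts))
  remaining <- sum(counts)
  for (i in seq_along(counts)) {
    if (k <= 0L) break
    ci <- counts[i]
    if (ci == 0L) next
    remaining <- remaining - ci
    x <- stats::rhyper(1L, m = ci, n = remaining, k = k)
    out[i] <- x
    k <- k - x
  }
  out
}

#' Convert read counts to within-sample relative abundances
#'
#' Each column is divided by its sum; all-zero samples stay zero and their ids
#' are recorded in the `empty_samples` attribute (with a warning).
#'
#' @param counts Numeric matrix, taxa x samples.
#' @return Matrix of fractions; non-empty columns sum to 1.
#' @export
to_relative <- function(counts) {
  assert_count_matrix(counts)
  totals <- colSums(counts)
  empty <- colnames(counts)[totals == 0]
  if (length(empty)) {
    warning("all-zero sample(s): ", paste(empty, collapse = ", "))
  }
  rel <- sweep(counts, 2L, pmax(totals, 1), "/")
  rel[, totals == 0] <- 0
  storage.mode(rel) <- "double"
  attr(rel, "empty_samples") <- empty
  rel
}

#' Assign WHO life-stage age groups
#'
#' G1 infants/young children (0-4 completed years, i.e. ages in `[0, 5)`),
#' G2 children/adolescents `[5, 18)`, G3 adults `[18, 65)`, G4 elderly
#' `[65, Inf)`. Half-open bins: every non-negative age maps to exactly one
#' group.
#'
#' @param age_years Numeric vector of ages in years (months as m/12).
#' @return Character vector of labels in `c("G1","G2","G3","G4")`.
#' @export
assign_age_group <- function(age_years) {
  if (anyNA(age_years) || any(age_years < 0)) {
    stop_agecore("ages must be non-negative and non-missing",
                 class = "agecore_parameter_error")
  }
  as.character(cut(age_years, breaks = c(0, 5, 18, 65, Inf),
                   labels = AGE_GROUPS, right = FALSE))
}

#' Assign early-life age subgroups
#'
#' G1a `[0, 1/12)` (first month), G1b `[1/12, 0.5)`, G1c `[0.5, 1)`,
#' G1d `[1, 5)`, G2a `[5, 11)`. Ages of 11 years and over have no defined
#' subgroup and return their plain age-group label.
#'
#' @inheritParams assign_age_group
#' @return Character vector of subgroup labels.
#' @export
assign_age_subgroup <- function(age_years) {
  if (anyNA(age_years) || any(age_years < 0)) {
    stop_agecore("ages must be non-negative and non-missing",
                 class = "agecore_parameter_error")
  }
  out <- assign_age_group(age_years)
  sub <- as.character(cut(age_years, breaks = c(0, 1 / 12, 0.5, 1, 5, 11),
                          labels = c("G1a", "G1b", "G1c", "G1d", "G2a"),
                          right = FALSE))
  ifelse(is.na(sub), out, sub)
}
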