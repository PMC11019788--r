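#' Literature-derived reference species profile
#'
#' The 29 representative human-gut species shared by the core and accessory
#' microbiota of all four WHO age groups in a pooled 6,653-sample
#' shallow-shotgun cohort, with their published per-group prevalence and mean
#' relative abundance and the published core flag per cell. Per-genus
#' `unknown_species` aggregate bins carry `named_species = FALSE`.
#'
#' @param long If `TRUE` (default) return one row per (taxon, age group);
#'   otherwise the wide table as shipped.
#' @return A data.frame. Long form: `taxon`, `named_species`, `group`,
#'   `prevalence` and `mean_rel_abundance` as fractions in `[0,1]`, and
#'   `core_reported` (logical, the published bold/core flag).
#' @export
reference_species_profile <- function(long = TRUE) {
  path <- system.file("extdata", "reference_species_profile.tsv",
                      package = "agecore", mustWork = TRUE)
  wide <- utils::read.delim(path, header = TRUE, sep = "\t",
                            comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
  wide$named_species <- wide$named_species == 1
  if (!long) return(wide)
  rows <- lapply(AGE_GROUPS, function(g) {
    data.frame(
      taxon = wide$taxon,
      named_species = wide$named_species,
      group = g,
      prevalence = wide[[paste0("prev_", g)]] / 100,
      mean_rel_abundance = wide[[paste0("abund_", g)]] / 100,
      core_reported = wide[[paste0("core_", g)]] == 1,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
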