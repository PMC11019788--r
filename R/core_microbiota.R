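#' Per-group taxon prevalence and mean relative abundance
#'
#' Prevalence is the fraction of the group's samples in which a taxon is
#' detected (relative abundance > 0 after subsampling); mean relative
#' abundance averages over ALL of the group's samples, zeros included, so the
#' two quantities decouple for rare-but-abundant taxa.
#'
#' @param rel Relative-abundance matrix (taxa x samples), e.g. [to_relative()].
#' @param metadata Metadata data.frame aligned to `colnames(rel)` with an
#'   `age_group` column (see [load_profile_table()]).
#' @param group Age-group label to summarise.
#' @return data.frame with `taxon`, `prevalence`, `mean_rel_abundance`.
#' @export
prevalence_and_abundance <- function(rel, metadata, group) {
  assert_count_matrix(rel, "relative-abundance table")
  idx <- which(metadata$age_group == group &
                 metadata$sample %in% colnames(rel))
  if (!length(idx)) {
    stop_agecore("no samples in group ", group, class = "agecore_group_error")
  }
  sub <- rel[, metadata$sample[idx], drop = FALSE]
  data.frame(
    taxon = rownames(sub),
    prevalence = rowMeans(sub > 0),
    mean_rel_abundance = rowMeans(sub),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Classify taxa as core, accessory or neither
#'
#' A taxon is *core* in a group when its prevalence is at least `core_prev`
#' (default 50%) and its mean relative abundance exceeds `min_abund` (default
#' 0.1%); *accessory* when prevalence lies in `[acc_prev, core_prev)` with the
#' same abundance requirement; *neither* otherwise. The prevalence bound is
#' inclusive at 50% and the abundance bound strict at 0.1%, the convention the
#' reference profile's reported core flags follow.
#'
#' @param prevalence,mean_rel_abundance Numeric vectors of fractions in
#'   `[0, 1]` (recycled against each other).
#' @param core_prev,acc_prev,min_abund Classification thresholds (fractions).
#' @return Character vector in `c("core", "accessory", "neither")`.
#' @export
classify_core_accessory <- function(prevalence, mean_rel_abundance,
                                    core_prev = 0.50, acc_prev = 0.30,
                                    min_abund = 0.001) {
  stopifnot(all(prevalence >= 0 & prevalence <= 1, na.rm = TRUE),
            all(mean_rel_abundance >= 0 & mean_rel_abundance <= 1,
                na.rm = TRUE))
  n <- max(length(prevalence), length(mean_rel_abundance))
  prevalence <- rep_len(prevalence, n)
  mean_rel_abundance <- rep_len(mean_rel_abundance, n)
  out <- rep("neither", n)
  abundant <- mean_rel_abundance > min_abund
  out[abundant & prevalence >= core_prev] <- "core"
  out[abundant & prevalence >= acc_prev & prevalence < core_prev] <- "accessory"
  out
}

#' Classify every taxon in every age group
#'
#' @inheritParams prevalence_and_abundance
#' @inheritParams classify_core_accessory
#' @param groups Age groups to classify (default all four).
#' @return data.frame with `group`, `taxon`, `prevalence`,
#'   `mean_rel_abundance`, `label`.
#' @export
classify_cohort <- function(rel, metadata, groups = AGE_GROUPS,
                            core_prev = 0.50, acc_prev = 0.30,
                            min_abund = 0.001) {
  out <- lapply(groups, function(g) {
    pa <- prevalence_and_abundance(rel, metadata, g)
    pa$label <- classify_core_accessory(pa$prevalence, pa$mean_rel_abundance,
                                        core_prev, acc_prev, min_abund)
    cbind(group = g, pa, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cross-group screening of core/accessory membership
#'
#' Given per-group classifications covering an identical taxon set in all four
#' age groups, derives the life-span membership sets: taxa that are core or
#' accessory in every group, taxa core in every group, taxa accessory in every
#' group, and taxa that are accessory in infancy (G1) but core in all later
#' groups (G2-G4) -- the accessory-to-core transition pattern.
#'
#' The ubiquity sets (`ubiquitous_core`, `ubiquitous_accessory`) are computed
#' over named species only when `named_only = TRUE` (default), excluding
#' per-genus `unknown_species` aggregate bins whose ubiquity reflects the
#' aggregation rather than a single species; the unrestricted sets are always
#' returned alongside.
#'
#' @param classifications data.frame as from [classify_cohort()], optionally
#'   with a logical `named_species` column (taxa matching `unknown_species`
#'   are otherwise treated as unnamed bins).
#' @param named_only Restrict ubiquity sets to named species.
#' @return A list of class `agecore_screen`: `labels` (taxon x group label
#'   matrix, Table-ordered by G1 prevalence descending),
#'   `all_groups_core_or_accessory`, `ubiquitous_core`,
#'   `ubiquitous_accessory`, `ubiquitous_core_any`, `ubiquitous_accessory_any`,
#'   `accessory_to_core_transitions` (character vectors of taxa).
#' @export
cross_group_screen <- function(classifications, named_only = TRUE) {
  needed <- c("group", "taxon", "label")
  if (!all(needed %in% names(classifications))) {
    stop_agecore("classifications need columns group/taxon/label",
                 class = "agecore_format_error")
  }
  sets <- split(classifications$taxon, classifications$group)
  if (!all(AGE_GROUPS %in% names(sets))) {
    stop_agecore("classifications must cover all four age groups",
                 class = "agecore_group_error")
  }
  base_set <- sort(unique(sets[[1L]]))
  for (g in AGE_GROUPS) {
    if (!identical(sort(unique(sets[[g]])), base_set)) {
      stop_agecore("taxon sets differ between age groups",
                   class = "agecore_alignment_error")
    }
  }
  labels <- matrix(NA_character_, nrow = length(base_set), ncol = 4L,
                   dimnames = list(base_set, AGE_GROUPS))
  for (g in AGE_GROUPS) {
    sub <- classifications[classifications$group == g, ]
    labels[sub$taxon, g] <- sub$label
  }
  ## Table-style ordering: G1 prevalence descending when available
  g1 <- classifications[classifications$group == "G1", ]
  if (!is.null(g1$prevalence)) {
    ord <- g1$taxon[order(-g1$prevalence)]
    labels <- labels[ord, , drop = FALSE]
  }
  if ("named_species" %in% names(classifications)) {
    named_map <- tapply(classifications$named_species, classifications$taxon,
                        function(x) all(x))
    named <- named_map[rownames(labels)]
  } else {
    named <- !grepl("unknown_species", rownames(labels), fixed = TRUE)
  }
  names(named) <- rownames(labels)
  in_all <- function(lab) rownames(labels)[rowSums(labels == lab) == 4L]
  core_any <- in_all("core")
  acc_any <- in_all("accessory")
  ok <- matrix(labels %in% c("core", "accessory"), nrow = nrow(labels))
  either <- rownames(labels)[rowSums(ok) == 4L]
  trans <- rownames(labels)[labels[, "G1"] == "accessory" &
                              labels[, "G2"] == "core" &
                              labels[, "G3"] == "core" &
                              labels[, "G4"] == "core"]
  restrict <- function(x) if (named_only) x[named[x]] else x
  structure(list(
    labels = labels,
    all_groups_core_or_accessory = either,
    ubiquitous_core = restrict(core_any),
    ubiquitous_accessory = restrict(acc_any),
    ubiquitous_core_any = core_any,
    ubiquitous_accessory_any = acc_any,
    accessory_to_core_transitions = trans
  ), class = "agecore_screen")
}
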