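#' Key-enzyme registry
#'
#' Maps Enzyme Commission numbers to diet/metabolite categories. The default
#' registry carries the printed key enzymes: beta-galactosidase (EC 3.2.1.23,
#' lactose/HMO), thiamine biosynthesis (EC 2.7.1.89, 2.7.1.50, 3.6.1.27),
#' niacin biosynthesis (EC 2.7.1.23, 6.3.5.1), plus representative fiber
#' (cellulase 3.2.1.4, xylanase 3.2.1.8), carbohydrate (glucokinase 2.7.1.2)
#' and SCFA (butyryl-CoA:acetate CoA-transferase 2.8.3.8) entries. User
#' categories can be appended from a two-column `ec<TAB>category` file.
#'
#' @param extra_path Optional path to a two-column TSV extending the registry.
#' @return data.frame with `ec` and `category`.
#' @export
key_enzyme_registry <- function(extra_path = NULL) {
  reg <- data.frame(
    ec = c("3.2.1.23",
           "2.7.1.89", "2.7.1.50", "3.6.1.27",
           "2.7.1.23", "6.3.5.1",
           "3.2.1.4", "3.2.1.8",
           "2.7.1.2",
           "2.8.3.8"),
    category = c("lactose/HMO",
                 "vitamin-thiamine", "vitamin-thiamine", "vitamin-thiamine",
                 "vitamin-niacin", "vitamin-niacin",
                 "fiber", "fiber",
                 "carbohydrate",
                 "SCFA"),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra_path)) {
    extra <- utils::read.delim(extra_path, header = FALSE, sep = "\t",
                               comment.char = "#",
                               col.names = c("ec", "category"),
                               stringsAsFactors = FALSE)
    stopifnot(all(is_valid_ec(extra$ec)))
    reg <- unique(rbind(reg, extra))
  }
  reg
}

#' Validate EC-number syntax
#'
#' Four dot-separated fields; the last may be `-` for partial classifications.
#' @param ec Character vector.
#' @return Logical vector.
#' @export
is_valid_ec <- function(ec) {
  grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)$", ec)
}

#' Species-by-enzyme Spearman correlation screen
#'
#' Correlates each age-associated taxon with each registry EC reaction
#' abundance across samples (Spearman, so any per-sample rescaling of the EC
#' table is immaterial), applies Benjamini-Hochberg FDR within the tested pair
#' set, and masks non-significant cells.
#'
#' @param species_rel Relative-abundance matrix restricted to the
#'   age-associated taxa (taxa x samples).
#' @param ec_table EC x samples abundance matrix (valid EC ids as rownames).
#' @param registry Registry data.frame (see [key_enzyme_registry()]); only its
#'   ECs are tested. Registry ECs absent from `ec_table` are reported in the
#'   `untested_ecs` attribute.
#' @param alpha Significance level on the q-value for masking (default 0.05).
#' @return data.frame of class `agecore_ec_corr`: `taxon`, `ec`, `category`,
#'   `rho`, `p_value`, `q_value`, `significant`, `rho_masked` (rho where
#'   significant, NA otherwise).
#' @export
species_ec_correlation <- function(species_rel, ec_table,
                                   registry = key_enzyme_registry(),
                                   alpha = 0.05) {
  assert_count_matrix(species_rel, "species table")
  assert_count_matrix(ec_table, "EC table")
  if (!all(is_valid_ec(rownames(ec_table)))) {
    stop_agecore("invalid EC identifiers in EC table",
                 class = "agecore_format_error")
  }
  common <- intersect(colnames(species_rel), colnames(ec_table))
  if (length(common) < 3L) {
    stop_agecore(">= 3 aligned samples required",
                 class = "agecore_alignment_error")
  }
  sp <- species_rel[, common, drop = FALSE]
  ec <- ec_table[, common, drop = FALSE]
  tested <- intersect(registry$ec, rownames(ec))
  untested <- setdiff(registry$ec, rownames(ec))
  grid <- expand.grid(taxon = rownames(sp), ec = tested,
                      stringsAsFactors = FALSE)
  stats_ <- mapply(function(tx, e) {
    ct <- suppressWarnings(
      stats::cor.test(sp[tx, ], ec[e, ], method = "spearman", exact = FALSE)
    )
    c(rho = unname(ct$estimate), p = ct$p.value)
  }, grid$taxon, grid$ec)
  out <- data.frame(grid,
                    category = registry$category[match(grid$ec, registry$ec)],
                    rho = stats_["rho", ], p_value = stats_["p", ],
                    stringsAsFactors = FALSE)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- !is.na(out$q_value) & out$q_value < alpha
  out$rho_masked <- ifelse(out$significant, out$rho, NA_real_)
  rownames(out) <- NULL
  attr(out, "untested_ecs") <- untested
  class(out) <- c("agecore_ec_corr", "data.frame")
  out
}

#' Per-(age group, EC category) mean signed correlation
#'
#' Averages the significant signed correlations over each age group's
#' characteristic taxa (those labelled core or accessory in that group) per
#' enzyme category, producing the group-by-category sign-pattern summary.
#'
#' @param correlations Output of [species_ec_correlation()].
#' @param classifications data.frame from [classify_cohort()] (columns
#'   `group`, `taxon`, `label`).
#' @return data.frame: `group`, `category`, `mean_rho` (NA when the group has
#'   no significant cell in that category), `n_cells`.
#' @export
group_enzyme_summary <- function(correlations, classifications) {
  groups <- unique(classifications$group)
  cats <- unique(correlations$category)
  out <- expand.grid(group = groups, category = cats,
                     stringsAsFactors = FALSE)
  out$mean_rho <- NA_real_
  out$n_cells <- 0L
  for (r in seq_len(nrow(out))) {
    g <- out$group[r]
    taxa_g <- classifications$taxon[classifications$group == g &
                                      classifications$label %in%
                                      c("core", "accessory")]
    cells <- correlations[correlations$taxon %in% taxa_g &
                            correlations$category == out$category[r] &
                            correlations$significant, , drop = FALSE]
    out$n_cells[r] <- nrow(cells)
    if (nrow(cells)) out$mean_rho[r] <- mean(cells$rho)
  }
  out
}
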