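#' Default run configuration
#'
#' Thresholds follow the study protocol: 100,000-read subsampling cap, core
#' prevalence 50%, accessory prevalence 30%, abundance floor 0.1%, Spearman
#' screen alpha 0.01, Tukey alpha 0.05, envfit alpha 0.005, geography alpha
#' 0.05, 999 permutations.
#'
#' @param ... Overrides of any default field.
#' @return A list of class `agecore_runconfig`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    profile = NULL, metadata = NULL, ec = NULL,   # input paths, or:
    simulate = NULL,                              # list passed to the generator
    cap = 100000L,
    core_prev = 0.50, acc_prev = 0.30, min_abund = 0.001,
    corr_alpha = 0.01, tukey_alpha = 0.05,
    envfit_alpha = 0.005, ec_alpha = 0.05, geo_alpha = 0.05,
    permutations = 999L,
    seed = 1L,
    outdir = "agecore_run"
  )
  over <- list(...)
  cfg[names(over)] <- over
  validate_run_config(structure(cfg, class = "agecore_runconfig"))
}

validate_run_config <- function(config) {
  thr <- c(config$core_prev, config$acc_prev, config$min_abund,
           config$corr_alpha, config$tukey_alpha, config$envfit_alpha,
           config$ec_alpha, config$geo_alpha)
  if (any(thr <= 0 | thr >= 1)) {
    stop_agecore("all thresholds must lie in (0,1)",
                 class = "agecore_config_error")
  }
  if (config$cap < 1) {
    stop_agecore("cap must be >= 1", class = "agecore_config_error")
  }
  if (is.null(config$simulate) &&
      (is.null(config$profile) || is.null(config$metadata))) {
    stop_agecore("config needs input paths (profile + metadata) or a ",
                 "simulate block", class = "agecore_config_error")
  }
  invisible(config)
}

#' Read a run configuration from a YAML file
#' @param path YAML file with the fields of [default_run_config()].
#' @return An `agecore_runconfig`.
#' @export
read_run_config <- function(path) {
  do.call(default_run_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes profiles -> diversity -> core/accessory classification -> age
#' screen -> functional correlations -> geography in order, writing every
#' stage's table under `config$outdir` together with a manifest (input file
#' hashes, seed, thresholds, package version) and a plain-text log. A single
#' global seed fans out into per-stage seeds by a fixed stage-name hash, so
#' identical config + seed reproduces every output.
#'
#' @param config An `agecore_runconfig` (see [default_run_config()] /
#'   [read_run_config()]).
#' @return Invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_all <- function(config) {
  validate_run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$outdir, "run.log")
  cat("", file = logfile)
  log_line <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), "|", ..., "\n",
        file = logfile, append = TRUE)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop_agecore("stage '", name, "' failed: ", conditionMessage(e),
                   class = "agecore_stage_error")
    })
  }
  manifest <- list(seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("agecore")),
                   thresholds = config[c("cap", "core_prev", "acc_prev",
                                         "min_abund", "corr_alpha",
                                         "tukey_alpha", "envfit_alpha",
                                         "ec_alpha", "geo_alpha",
                                         "permutations")],
                   inputs = list(), outputs = list())

  ## ---- profiles ----
  dat <- stage("profiles", {
    if (!is.null(config$simulate)) {
      gen_cfg <- do.call(default_synthetic_config, config$simulate)
      cohort <- generate_cohort(gen_cfg, seed = stage_seed(config$seed,
                                                           "simulate"))
      list(counts = cohort$counts, metadata = cohort$metadata,
           ec = cohort$ec)
    } else {
      x <- load_profile_table(config$profile, config$metadata)
      x$ec <- if (!is.null(config$ec)) read_ec_table(config$ec) else NULL
      manifest$inputs <<- lapply(
        Filter(Negate(is.null),
               config[c("profile", "metadata", "ec")]),
        function(p) unname(tools::md5sum(p)))
      x
    }
  })
  counts <- subsample_reads(dat$counts, cap = config$cap,
                            seed = stage_seed(config$seed, "subsample"))
  rel <- to_relative(counts)
  meta <- dat$metadata
  log_line("profiles:", nrow(counts), "taxa,", ncol(counts),
           "samples, cap", config$cap)

  outputs <- list()
  put <- function(name, obj) {
    path <- file.path(config$outdir, name)
    if (is.matrix(obj)) {
      write_profile_table(obj, path)
    } else {
      utils::write.table(obj, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    outputs[[name]] <<- unname(tools::md5sum(path))
    invisible(path)
  }
  put("profile_subsampled.tsv", counts)
  put("metadata.tsv", meta)

  ## ---- diversity ----
  div <- stage("diversity", {
    alpha_tab <- data.frame(sample = colnames(counts),
                            richness = richness(counts),
                            shannon = shannon(rel + 0),
                            age_group = meta$age_group,
                            row.names = NULL)
    rich_cld <- pairwise_kruskal(alpha_tab$richness, alpha_tab$age_group,
                                 alpha = 0.05)
    shan_cld <- pairwise_kruskal(alpha_tab$shannon, alpha_tab$age_group,
                                 alpha = 0.05)
    D <- bray_curtis(rel)
    ord <- pcoa(D, k = 2L)
    glob <- permanova(D, meta$age_group, n_perm = config$permutations,
                      seed = stage_seed(config$seed, "permanova"))
    pw <- pairwise_permanova(D, meta$age_group,
                             n_perm = config$permutations,
                             seed = stage_seed(config$seed, "pairwise"))
    fit <- envfit_ord(ord, data.frame(age_years = meta$age_years),
                      n_perm = config$permutations,
                      seed = stage_seed(config$seed, "envfit"))
    list(alpha = alpha_tab, richness_letters = rich_cld,
         shannon_letters = shan_cld, ordination = ord, global = glob,
         pairwise = pw, envfit = fit)
  })
  put("diversity_alpha.tsv", div$alpha)
  put("diversity_pairwise_permanova.tsv", div$pairwise)
  put("diversity_envfit.tsv", div$envfit)
  log_line("diversity: global PERMANOVA F =",
           signif(div$global$pseudo_F, 4), "p =", div$global$p_value)

  ## ---- core microbiota ----
  core <- stage("core_microbiota", {
    cls <- classify_cohort(rel, meta, core_prev = config$core_prev,
                           acc_prev = config$acc_prev,
                           min_abund = config$min_abund)
    list(classifications = cls, screen = cross_group_screen(cls))
  })
  put("core_classification.tsv", core$classifications)
  log_line("core: ",
           length(core$screen$all_groups_core_or_accessory),
           "taxa core-or-accessory in all groups")

  ## ---- age screen ----
  scr <- stage("correlation_screen", {
    s1 <- spearman_age_screen(rel, meta, alpha = config$corr_alpha)
    s2 <- anova_tukey_filter(rel, meta, alpha = config$tukey_alpha)
    select_age_associated(s1, s2)
  })
  put("age_screen.tsv", scr$results)
  log_line("screen:", sum(scr$results$selected), "selected (",
           length(scr$negative_with_age), "negative,",
           length(scr$positive_with_age), "positive )")

  ## ---- functional layer ----
  fun <- stage("function_profile", {
    if (is.null(dat$ec) || !sum(scr$results$selected)) return(NULL)
    sel_taxa <- scr$results$taxon[scr$results$selected]
    corr <- species_ec_correlation(rel[sel_taxa, , drop = FALSE], dat$ec,
                                   alpha = config$ec_alpha)
    list(correlations = corr,
         summary = group_enzyme_summary(corr, core$classifications))
  })
  if (!is.null(fun)) {
    put("function_correlations.tsv", as.data.frame(fun$correlations))
    put("function_summary.tsv", fun$summary)
    log_line("function:", sum(fun$correlations$significant),
             "significant species-EC cells")
  }

  ## ---- geography ----
  geo <- stage("geography", {
    assoc <- geo_associate(rel, meta, alpha = config$geo_alpha)
    list(associations = assoc, consistent = consistency_filter(assoc))
  })
  put("geography.tsv", geo$associations)
  put("geography_consistent.tsv", geo$consistent)
  log_line("geography:", sum(geo$associations$significant),
           "significant contrasts,",
           sum(geo$consistent$consistent), "consistent across groups")

  manifest$outputs <- outputs
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(diversity = div, core = core, screen = scr,
                 functional = fun, geography = geo, manifest = manifest))
}

#' Read an EC reaction-abundance table
#'
#' TSV in the profile layout (first column EC id, sample columns); ids must be
#' syntactically valid EC numbers.
#' @param path Path to the TSV.
#' @return Numeric matrix, EC x samples.
#' @export
read_ec_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  if (!all(is_valid_ec(rownames(m)))) {
    stop_agecore("invalid EC identifiers in ", path,
                 class = "agecore_format_error")
  }
  assert_count_matrix(m, "EC table")
  m
}
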