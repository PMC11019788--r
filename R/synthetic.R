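#' Default synthetic-cohort configuration
#'
#' Builds the generator truth used throughout the test suite. The 29 reference
#' species carry their published per-age-group prevalence and mean relative
#' abundance (see [reference_species_profile()]); four additional
#' geography-marker species (Segatella/Prevotellamassilia/Treponema/Alistipes
#' types, absent from the reference table but needed to express continent
#' effects) carry modelled parameters. A per-group pool of low-abundance
#' filler species completes the group richness targets (42/84/83/86 mean
#' observed species for G1-G4).
#'
#' Within-carrier abundance is log-normal: a taxon with prevalence `pi` and
#' all-sample mean relative abundance `mu` is present in a sample with
#' probability `pi` and, when present, drawn from
#' `LogNormal(log(mu/pi) - sigma^2/2, sigma)`, so the expected mean over all
#' samples (zeros included) equals `mu` -- the quantity
#' [prevalence_and_abundance()] estimates.
#'
#' @param n_per_group Named integer vector of samples per age group.
#' @param sigma Log-scale dispersion of within-carrier abundance.
#' @param n_filler Size of the filler species pool.
#' @param continent_proportions Named sampling weights for continents
#'   (Europe is the reference population).
#' @return A list of class `agecore_config`; see fields in the source. All
#'   entries are plain vectors/data.frames and serialise with
#'   [write_cohort()].
#' @export
default_synthetic_config <- function(n_per_group = c(G1 = 500, G2 = 500,
                                                     G3 = 500, G4 = 500),
                                     sigma = 1.0, n_filler = 150L,
                                     continent_proportions = c(
                                       "Europe" = 0.55,
                                       "North America" = 0.15,
                                       "Asia" = 0.12,
                                       "South America" = 0.10,
                                       "Africa" = 0.08)) {
  ref <- reference_species_profile(long = TRUE)
  species <- data.frame(
    taxon = ref$taxon, group = ref$group,
    prevalence = ref$prevalence, mean_abundance = ref$mean_rel_abundance,
    sigma = sigma, named_species = ref$named_species, in_reference = TRUE,
    stringsAsFactors = FALSE
  )
  ## Geography-marker species: adult-associated, parameters are modelling
  ## choices (sub-threshold in G1 so the reference screen is unaffected).
  extras <- expand.grid(taxon = c("Segatella copri",
                                  "Prevotellamassilia unknown_species",
                                  "Treponema unknown_species",
                                  "Alistipes putredinis"),
                        group = AGE_GROUPS, stringsAsFactors = FALSE)
  pars <- list(
    "Segatella copri" = list(p = c(0.10, 0.30, 0.35, 0.30),
                             m = c(0.005, 0.020, 0.025, 0.020)),
    "Prevotellamassilia unknown_species" = list(p = c(0.05, 0.15, 0.18, 0.15),
                                                m = c(0.0010, 0.0040,
                                                      0.0050, 0.0040)),
    "Treponema unknown_species" = list(p = c(0.03, 0.08, 0.10, 0.08),
                                       m = c(0.0005, 0.0020, 0.0020, 0.0020)),
    "Alistipes putredinis" = list(p = c(0.15, 0.60, 0.65, 0.60),
                                  m = c(0.0020, 0.0100, 0.0120, 0.0100))
  )
  gi <- match(extras$group, AGE_GROUPS)
  extras$prevalence <- mapply(function(t, i) pars[[t]]$p[i], extras$taxon, gi)
  extras$mean_abundance <- mapply(function(t, i) pars[[t]]$m[i],
                                  extras$taxon, gi)
  extras$sigma <- sigma
  extras$named_species <- !grepl("unknown_species", extras$taxon)
  extras$in_reference <- FALSE
  species <- rbind(species, extras[, names(species)])
  rownames(species) <- NULL

  structure(list(
    species = species,
    richness_target = c(G1 = 42, G2 = 84, G3 = 83, G4 = 86),
    n_filler = as.integer(n_filler),
    filler_decay = 0.97,
    filler_sigma = 0.7,
    n_per_group = n_per_group,
    age_range = list(G1 = c(0, 5), G2 = c(5, 18), G3 = c(18, 65),
                     G4 = c(65, 100)),
    ## classified-read depth: log-normal around the cohort mean, censored at
    ## the 100,000-read shallow-shotgun cap
    depth = list(mean = 63771, sd = 13611, cap = 100000),
    continent_proportions = continent_proportions,
    reference_continent = "Europe",
    ## Prevotella/Treponema-type markers expand in South America/Africa in
    ## both carriage (odds scale) and load; Bacteroides-type taxa keep their
    ## carriage but at reduced load, so reference-species prevalence is
    ## unaffected by the continent mix.
    continent_effects = data.frame(
      continent = rep(c("South America", "Africa"), each = 2L),
      pattern = rep(c("^(Segatella|Prevotella|Treponema)",
                      "^(Bacteroides|Phocaeicola|Alistipes)"), 2L),
      fold = rep(c(4, 0.25), 2L),
      fold_carriage = rep(c(4, 1), 2L),
      stringsAsFactors = FALSE
    ),
    ec_registry = key_enzyme_registry(),
    ec_incidence = default_ec_incidence(),
    ec_noise_scale = 0.1
  ), class = "agecore_config")
}

## Default species -> EC carriage map: infant-associated enzymes (lactose,
## thiamine, niacin) sit on Bifidobacterium/E. coli, fiber and SCFA enzymes on
## adult-associated Bacteroides/Roseburia/Faecalibacterium types.
default_ec_incidence <- function() {
  links <- list(
    "3.2.1.23" = c("Bifidobacterium longum", "Bifidobacterium unknown_species",
                   "Escherichia coli"),
    "2.7.1.89" = c("Bifidobacterium longum", "Escherichia coli"),
    "2.7.1.50" = c("Bifidobacterium longum", "Escherichia coli"),
    "3.6.1.27" = c("Bifidobacterium longum", "Escherichia coli"),
    "2.7.1.23" = c("Escherichia coli", "Bifidobacterium longum"),
    "6.3.5.1"  = c("Escherichia coli", "Bifidobacterium longum"),
    "3.2.1.4"  = c("Bacteroides uniformis", "Bacteroides ovatus",
                   "Bacteroides xylanisolvens", "Roseburia intestinalis"),
    "3.2.1.8"  = c("Bacteroides uniformis", "Bacteroides ovatus",
                   "Agathobacter rectalis"),
    "2.7.1.2"  = c("Escherichia coli", "Blautia wexlerae",
                   "Faecalibacterium prausnitzii", "Bacteroides uniformis"),
    "2.8.3.8"  = c("Faecalibacterium prausnitzii", "Roseburia intestinalis",
                   "Anaerostipes hadrus", "Agathobacter rectalis")
  )
  taxa <- sort(unique(unlist(links)))
  m <- matrix(0L, nrow = length(taxa), ncol = length(links),
              dimnames = list(taxa, names(links)))
  for (ec in names(links)) m[links[[ec]], ec] <- 1L
  m
}

validate_synthetic_config <- function(config) {
  sp <- config$species
  if (any(sp$prevalence < 0 | sp$prevalence > 1)) {
    stop_agecore("species prevalence outside [0,1]",
                 class = "agecore_config_error")
  }
  if (any(sp$prevalence > 0 & sp$mean_abundance <= 0) || any(sp$sigma <= 0)) {
    stop_agecore("species mean abundance/sigma must be positive",
                 class = "agecore_config_error")
  }
  if (any(config$continent_effects$fold <= 0) ||
      any(config$continent_effects$fold_carriage <= 0)) {
    stop_agecore("continent fold-changes must be positive",
                 class = "agecore_config_error")
  }
  invisible(config)
}

#' Generate a synthetic age-structured cohort
#'
#' Draws, per sample: an age uniform within its group's range, a continent,
#' Bernoulli presence per species, log-normal within-carrier abundances,
#' continent fold-changes, renormalisation to a composition, a censored
#' log-normal classified-read depth and a multinomial count draw. EC reaction
#' abundances are incidence-weighted sums of species compositions plus
#' truncated Gaussian noise. Fully reproducible given `seed`.
#'
#' @param config An `agecore_config`, e.g. [default_synthetic_config()].
#' @param seed Integer seed.
#' @return A list of class `agecore_cohort`: `counts` (integer taxa x samples),
#'   `metadata`, `ec` (EC x samples), `composition` (latent taxa x samples)
#'   and `truth` (the config).
#' @export
generate_cohort <- function(config, seed = 1L) {
  validate_synthetic_config(config)
  groups <- names(config$n_per_group)
  if (any(config$n_per_group == 0)) {
    warning("empty age group(s): ",
            paste(groups[config$n_per_group == 0], collapse = ", "))
  }
  taxa_sp <- unique(config$species$taxon)
  filler <- if (config$n_filler > 0) {
    sprintf("synthetic_filler_%03d unknown_species",
            seq_len(config$n_filler))
  } else {
    character()
  }
  taxa <- c(taxa_sp, filler)
  cont_names <- names(config$continent_proportions)
  fold_lookup <- matrix(1, nrow = length(taxa), ncol = length(cont_names),
                        dimnames = list(taxa, cont_names))
  carr_lookup <- fold_lookup
  eff_tab <- config$continent_effects
  if (is.null(eff_tab$fold_carriage)) eff_tab$fold_carriage <- 1
  eff_tab <- eff_tab[eff_tab$continent %in% cont_names, , drop = FALSE]
  for (r in seq_len(nrow(eff_tab))) {
    eff <- eff_tab[r, ]
    hit <- grepl(eff$pattern, taxa)
    fold_lookup[hit, eff$continent] <-
      fold_lookup[hit, eff$continent] * eff$fold
    carr_lookup[hit, eff$continent] <-
      carr_lookup[hit, eff$continent] * eff$fold_carriage
  }

  with_seed(seed, {
    comp_blocks <- list()
    meta_blocks <- list()
    counter <- 0L
    for (g in groups) {
      n <- config$n_per_group[[g]]
      if (n == 0) next
      sp <- config$species[config$species$group == g, ]
      sp <- sp[match(taxa_sp, sp$taxon), ]
      pi_sp <- ifelse(is.na(sp$prevalence), 0, sp$prevalence)
      mu_sp <- ifelse(is.na(sp$mean_abundance), 0, sp$mean_abundance)
      sig_sp <- ifelse(is.na(sp$sigma), 1, sp$sigma)
      meanlog_sp <- ifelse(pi_sp > 0,
                           log(pmax(mu_sp, 1e-12) / pmax(pi_sp, 1e-12)) -
                             sig_sp^2 / 2,
                           -Inf)

      ## filler pool: presence probability chosen so expected total richness
      ## (species + filler) meets the group target; geometric carrier-mean
      ## series scaled so the expected composition sums to ~1 pre-renorm
      if (config$n_filler > 0) {
        p_f <- (config$richness_target[[g]] - sum(pi_sp)) / config$n_filler
        p_f <- min(max(p_f, 0.01), 0.95)
        dec <- config$filler_decay
        series <- dec^seq_len(config$n_filler)
        mass <- max(0.05, 1 - sum(mu_sp))
        a <- series * mass / (p_f * sum(series))
        pi_all <- c(pi_sp, rep(p_f, config$n_filler))
        sig_all <- c(sig_sp, rep(config$filler_sigma, config$n_filler))
        meanlog_all <- c(meanlog_sp, log(a) - config$filler_sigma^2 / 2)
      } else {
        pi_all <- pi_sp
        sig_all <- sig_sp
        meanlog_all <- meanlog_sp
      }

      nt <- length(taxa)
      cont <- sample(cont_names, n, replace = TRUE,
                     prob = config$continent_proportions)
      ## carriage folds act on the odds scale so probabilities stay in [0,1]
      odds <- pi_all / pmax(1 - pi_all, 1e-12)
      pi_mat <- odds * carr_lookup[, cont, drop = FALSE]
      pi_mat <- pi_mat / (1 + pi_mat)
      pi_mat[pi_all >= 1, ] <- 1
      pi_mat[pi_all <= 0, ] <- 0
      pres <- matrix(stats::rbinom(nt * n, 1L, pi_mat), nrow = nt)
      lat <- matrix(stats::rlnorm(nt * n, meanlog = meanlog_all,
                                  sdlog = sig_all), nrow = nt)
      lat[meanlog_all == -Inf, ] <- 0
      w <- pres * lat
      w <- w * fold_lookup[, cont, drop = FALSE]
      cs <- colSums(w)
      if (any(cs == 0)) {          # degenerate sample: fall back to uniform
        w[, cs == 0] <- 1 / nt
        cs[cs == 0] <- 1
      }
      comp <- sweep(w, 2L, cs, "/")
      rownames(comp) <- taxa

      ages <- stats::runif(n, config$age_range[[g]][1L],
                           config$age_range[[g]][2L])
      ids <- sprintf("S%05d", counter + seq_len(n))
      counter <- counter + n
      colnames(comp) <- ids
      comp_blocks[[g]] <- comp
      meta_blocks[[g]] <- data.frame(
        sample = ids, age_years = ages, continent = cont,
        cohort = paste0("BP", match(cont, cont_names)),
        stringsAsFactors = FALSE
      )
    }
    comp <- do.call(cbind, comp_blocks)
    meta <- do.call(rbind, meta_blocks)
    rownames(meta) <- NULL
    meta$age_group <- assign_age_group(meta$age_years)
    meta$age_subgroup <- assign_age_subgroup(meta$age_years)

    ## classified-read depth, censored at the shallow-shotgun cap
    dm <- config$depth
    cv2 <- (dm$sd / dm$mean)^2
    sdlog <- sqrt(log1p(cv2))
    meanlog <- log(dm$mean) - sdlog^2 / 2
    depth <- pmin(round(stats::rlnorm(ncol(comp), meanlog, sdlog)), dm$cap)
    depth <- pmax(depth, 1)

    counts <- vapply(seq_len(ncol(comp)), function(j) {
      stats::rmultinom(1L, size = depth[j], prob = comp[, j])[, 1L]
    }, integer(length(taxa)))
    dimnames(counts) <- dimnames(comp)

    ## EC layer: incidence-weighted species compositions + truncated noise
    inc <- config$ec_incidence
    present <- intersect(rownames(inc), taxa)
    signal <- t(inc[present, , drop = FALSE]) %*%
      comp[present, , drop = FALSE]
    noise_sd <- apply(signal, 1L, stats::sd) * config$ec_noise_scale
    noise_sd[!is.finite(noise_sd)] <- 0
    noise <- matrix(stats::rnorm(length(signal), 0,
                                 rep(pmax(noise_sd, 1e-12),
                                     ncol(signal))),
                    nrow = nrow(signal))
    ec <- pmax(signal + noise, 0)
    dimnames(ec) <- dimnames(signal)

    structure(list(counts = counts, metadata = meta, ec = ec,
                   composition = comp, truth = config),
              class = "agecore_cohort")
  })
}

#' Recover generator truth from a synthetic cohort
#'
#' Estimates per-(taxon, group) prevalence and mean relative abundance with
#' exactly the estimators the core/accessory screen uses
#' ([prevalence_and_abundance()] on [to_relative()] counts) and reports them
#' against the generator truth.
#'
#' @param cohort An `agecore_cohort`.
#' @param reference_only Restrict to the 29 reference species (default) or
#'   report every configured species.
#' @return data.frame with `taxon`, `group`, true/estimated prevalence and
#'   abundance, and their differences.
#' @export
recover_parameters <- function(cohort, reference_only = TRUE) {
  stopifnot(inherits(cohort, "agecore_cohort"))
  rel <- to_relative(cohort$counts)
  truth <- cohort$truth$species
  if (reference_only) truth <- truth[truth$in_reference, ]
  out <- lapply(unique(truth$group), function(g) {
    est <- prevalence_and_abundance(rel, cohort$metadata, g)
    tg <- truth[truth$group == g, ]
    i <- match(tg$taxon, est$taxon)
    data.frame(
      taxon = tg$taxon, group = g,
      true_prevalence = tg$prevalence,
      est_prevalence = est$prevalence[i],
      true_abundance = tg$mean_abundance,
      est_abundance = est$mean_rel_abundance[i],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out$prevalence_error <- out$est_prevalence - out$true_prevalence
  out$abundance_error <- out$est_abundance - out$true_abundance
  rownames(out) <- NULL
  out
}

#' Write a synthetic cohort as plain-text tables
#'
#' Writes `profile.tsv`, `metadata.tsv`, `ec.tsv` and the generator truth
#' (`truth.yml`) under `dir`, in the formats [load_profile_table()] reads.
#' @param cohort An `agecore_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "agecore_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_profile_table(cohort$counts, file.path(dir, "profile.tsv"))
  utils::write.table(cohort$metadata[, c("sample", "age_years", "continent",
                                         "cohort")],
                     file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_profile_table(cohort$ec, file.path(dir, "ec.tsv"))
  truth <- cohort$truth
  truth$ec_incidence <- NULL   # matrix; re-derivable from the default config
  yaml::write_yaml(unclass(truth), file.path(dir, "truth.yml"))
  invisible(dir)
}
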