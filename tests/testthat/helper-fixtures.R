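## Shared fixtures and independent oracles, built in code at test time.

toy_counts <- function() {
  matrix(c(10L, 5L, 0L,
           0L, 5L, 20L),
         nrow = 3L,
         dimnames = list(c("Genus one", "Genus two", "Genus three"),
                         c("s1", "s2")))
}

write_toy_tables <- function(dir = tempfile("agecore"),
                             counts = toy_counts(),
                             ages = c(0.5, 30)) {
  dir.create(dir, showWarnings = FALSE)
  ppath <- file.path(dir, "profile.tsv")
  mpath <- file.path(dir, "metadata.tsv")
  write_profile_table(counts, ppath)
  meta <- data.frame(sample = colnames(counts), age_years = ages,
                     continent = "Europe", cohort = "BP1")
  utils::write.table(meta, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(profile = ppath, metadata = mpath, dir = dir)
}

## Metadata frame for in-memory matrices.
make_meta <- function(samples, ages, continent = "Europe", cohort = "BP1") {
  data.frame(sample = samples, age_years = ages,
             continent = rep_len(continent, length(samples)),
             cohort = rep_len(cohort, length(samples)),
             age_group = assign_age_group(ages),
             age_subgroup = assign_age_subgroup(ages),
             stringsAsFactors = FALSE)
}

## Independent step-up Benjamini-Hochberg, written from the definition.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## Small single-group cohort config built from the default scaffolding.
custom_config <- function(species, n_per_group, n_filler = 0L,
                          continent_proportions = c(Europe = 1)) {
  cfg <- default_synthetic_config(
    n_per_group = n_per_group,
    continent_proportions = continent_proportions)
  cfg$species <- species
  cfg$n_filler <- as.integer(n_filler)
  cfg
}

species_row <- function(taxon, group, prevalence, mean_abundance,
                        sigma = 1) {
  data.frame(taxon = taxon, group = group, prevalence = prevalence,
             mean_abundance = mean_abundance, sigma = sigma,
             named_species = TRUE, in_reference = FALSE,
             stringsAsFactors = FALSE)
}
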