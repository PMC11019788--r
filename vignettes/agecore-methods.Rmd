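---
title: "Methods: age-stratified core/accessory analysis of gut metagenome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-stratified core/accessory analysis of gut metagenome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agecore)
```

# The analysis

`agecore` implements a pooled life-span analysis of human gut microbiome
profiles from shallow shotgun sequencing. The input is a species-level
classified-read count table (taxa × samples, including per-genus
`unknown_species` bins), per-sample metadata (age, continent, cohort), and
optionally an EC-number reaction-abundance table. The pipeline:

1. caps every sample at 100,000 classified reads (shallow-shotgun protocol),
2. stratifies samples into WHO age groups — G1 (0–4 y), G2 (5–17 y),
   G3 (18–64 y), G4 (65 y+) — with early-life subgroups G1a–G2a,
3. computes alpha diversity (richness, Shannon) with pairwise Kruskal-Wallis
   compact letters, and beta diversity (Bray-Curtis, PCoA, PERMANOVA,
   envfit-style vector fitting),
4. classifies every taxon per age group as **core** (prevalence ≥ 50% and
   mean relative abundance > 0.1%), **accessory** (prevalence 30–50%, same
   abundance floor) or neither, and screens for cross-group patterns,
5. runs a two-stage age-association screen (Spearman with age at p < 0.01
   plus ANOVA/Tukey group enrichment at p < 0.05),
6. correlates age-associated species with key dietary/vitamin enzymes
   (EC numbers), and
7. fits a MaAsLin2-style multivariable continent model per age group with
   Europe as the reference population.

Since the original 6,653-sample cohort is not redistributable, a calibrated
synthetic cohort generator stands in for it; every stage is tested against
the generator's known truth and, where published numbers are re-derivable
from the shipped reference table, against those numbers exactly.

# Age boundaries

Groups are half-open on years: G1 = [0, 5), G2 = [5, 18), G3 = [18, 65),
G4 = [65, ∞), so every age maps to exactly one group and a 4-year-old is G1
("0–4 years" in completed years, WHO-style integer bins). Months are
fractional years (m/12). Subgroups: G1a [0, 1/12), G1b [1/12, 0.5),
G1c [0.5, 1), G1d [1, 5), G2a [5, 11). No finer partition is defined beyond
11 years, so older ages simply return their group label rather than a
guessed subgroup.

# Subsampling

The shallow-shotgun cap operates on classified-read counts per taxon as a
multivariate hypergeometric draw — statistically identical to subsampling
raw reads uniformly without replacement and re-classifying them, without
modelling the classifier. Samples at or below the cap are untouched
("up to" 100,000 reads). The draw is sequential (`rhyper` per taxon against
the remaining pool), exact, and deterministic given a seed; expected
relative abundances are unchanged, which the test suite verifies over
repeated draws.

# Core/accessory classification

Presence is any nonzero count after subsampling; prevalence is the fraction
of a group's samples with presence; mean relative abundance averages over
*all* group samples, zeros included. That convention lets prevalence and
abundance decouple (rare-but-abundant taxa such as *B. fragilis*). The core
rule is inclusive at the prevalence boundary (≥ 50%) and strict at the
abundance floor (> 0.1%): this is the only convention consistent with every
reported core flag of the 29-species reference profile shipped in
`inst/extdata/` (a cell at 50.58% prevalence is core; 48.39% is not). The
accessory band is [30%, 50%).

Cross-group screening derives life-span sets: taxa core-or-accessory in all
four groups, taxa core everywhere, accessory everywhere, and the
accessory-in-infancy → core-in-later-life transitions. The ubiquity sets
are restricted to named species by default: per-genus `unknown_species`
bins aggregate many species, so their near-universal prevalence reflects
the binning rather than a single organism's ubiquity (with them included,
four genus bins would join *B. uniformis* as all-group core members; the
unrestricted sets remain available as `*_any`). Classification itself
treats the bins as ordinary species-level taxa. Applying the thresholds to
the shipped reference values yields 20 accessory→core transition taxa; a
published tally of 21 evidently involves a rounding or inclusion nuance at
a band boundary that the printed two-decimal values cannot resolve, so the
transition count is reported but not treated as a fixed point.

# Diversity statistics

All beta-diversity machinery is implemented from the definitions (vegan and
ape serve as independent cross-checks in the tests, not as the
implementation):

* **Bray-Curtis**: `d(x,y) = 1 − 2Σmin(x_i,y_i)/(Σx_i + Σy_i)`, computed on
  relative abundances so depth-capped samples are comparable; the
  equivalent `Σ|x−y|/(Σx+Σy)` form is used for speed.
* **PCoA**: Gower double-centering of `−½D²`, symmetric eigendecomposition,
  coordinates scaled by `√λ`. Negative eigenvalues (Bray-Curtis is
  non-Euclidean) are dropped and their magnitude reported; no
  Lingoes/Cailliez correction, matching common practice.
* **PERMANOVA**: `SS_total = Σ_{i<j} d²_ij / n`, `SS_within` accumulated per
  group, pseudo-F = `(SS_B/(k−1))/(SS_W/(n−k))`, p by label permutation with
  the add-one convention, so the minimal attainable p is `1/(n_perm+1)`
  (default 999 permutations). An exhaustive mode enumerates all label
  permutations for small n and is checked against brute-force enumeration.
  Pairwise runs are BH-adjusted to q-values.
* **envfit**: least-squares regression of each centered variable on the
  ordination axes; `r² = 1 − RSS/TSS`; direction is the unit coefficient
  vector; significance by permuting the variable.
* **Compact letters**: the insertion algorithm (split columns on each
  significant pair, absorb subsets), so two groups share a letter exactly
  when their pairwise Kruskal-Wallis test is non-significant at α. Pairwise
  p-values are raw by default — the convention of the reported analyses —
  with BH correction available as an option.
* **Shannon** uses the natural log (exposed as an option).

# Age-association screen

Stage 1 computes Spearman's ρ of each taxon's relative abundance against
age in years (continuous, not group codes), with average-rank ties and the
asymptotic t approximation, and applies the stage threshold to the *raw*
p-value (p < 0.01) while always reporting BH q-values alongside — the
source protocol describes FDR correction applied to already-significant
results, and both thresholds are options. Stage 2 requires enrichment:
one-way ANOVA across G1–G4 followed by Tukey's HSD; a group is flagged when
its mean exceeds another group's at Tukey p < 0.05. Selection is the
conjunction, partitioned by the sign of ρ. Abundances enter untransformed
by default (an arcsine-square-root option exists).

# Functional layer

EC reaction abundances are treated as continuous and compared by Spearman
rank correlation, so any global rescaling of the table is immaterial. The
registry ships the printed key enzymes — beta-galactosidase 3.2.1.23
(lactose/HMO), thiamine 2.7.1.89/2.7.1.50/3.6.1.27, niacin
2.7.1.23/6.3.5.1 — plus representative fiber, carbohydrate and SCFA
entries, and is user-extensible from a two-column file; no attempt is made
to guess the full unpublished enzyme panel. P-values are BH-corrected
within the tested (taxon × EC) set and non-significant cells masked; the
group summary averages significant signed correlations over each group's
core/accessory taxa per category.

# Continent model

The multivariable geography model replicates MaAsLin2's default chain as a
documented approximation (the original tool's version/settings are
unstated): total-sum scaling, log2 transform with a half-minimum
pseudocount per feature, ordinary linear model on continent indicator
contrasts with Europe as reference, BH within age group, fitted separately
per age group; cells with fewer than 5 samples are not fitted. No random
effect for cohort/BioProject is included (none is described); this is an
extension point. The consistency filter keeps feature-contrasts significant
with the same sign in every fitted age group.

# The synthetic cohort generator

The generator is the package's stand-in for the pooled cohort and defines
the conditions every stochastic test runs under.

* **Species truth.** The 29 reference species carry their published
  per-group prevalence π and mean relative abundance μ. Carriage is
  Bernoulli(π); within-carrier abundance is log-normal with
  `meanlog = log(μ/π) − σ²/2`, so the expectation over all samples (zeros
  included) equals μ — exactly the estimator the classification uses. The
  published table gives no dispersion, so σ = 1 is a modelling default
  (exposed in the config); it reproduces the prevalence/abundance
  decoupling visible in the reference profile.
* **Richness.** Per-group filler pools complete the observed richness
  targets (42/84/83/86 mean species for G1–G4). Filler presence
  probability is set so expected total richness (reference + markers +
  filler) hits the target; filler carrier abundances follow a geometric
  series scaled so the expected composition sums to 1, keeping
  renormalisation nearly bias-free. The filler series floor (~10⁻³
  relative abundance) keeps detection near-certain at the ~64k-read depth,
  so observed richness ≈ carriage richness.
* **Depth.** Classified reads per sample are log-normal with mean 63,771
  and SD 13,611 (the reported cohort moments), censored at the 100,000
  cap.
* **Geography.** South America and Africa up-weight
  Prevotella/Treponema-type marker species ×4 in both carriage (odds
  scale) and load, and down-weight Bacteroides/Phocaeicola/Alistipes-type
  taxa ×0.25 in load only. Acting on carriage for the markers reflects the
  ecology (these taxa are carried far more often in those populations) and
  gives the effect detectable power at realistic sample sizes; acting on
  load only for the Bacteroides group leaves reference-species prevalence
  unaffected by the continent mix, so the published prevalence values stay
  the marginal truth. Magnitudes are free parameters; only the sign
  structure is asserted by tests. The markers themselves (*Segatella
  copri*, *Prevotellamassilia*, *Treponema*, *Alistipes putredinis*) carry
  modelled parameters kept sub-threshold in G1 so the 29-species reference
  screen is unaffected.
* **EC layer.** Reaction abundance is the incidence-weighted sum of linked
  species compositions plus truncated Gaussian noise with SD = 0.1 × the
  signal's SD. The default incidence map places lactose/thiamine/niacin
  enzymes on infant-associated taxa (*B. longum*, *E. coli*) and
  fiber/SCFA enzymes on adult-associated taxa.

What the generator does **not** emulate: compositional interactions between
taxa (presence/abundance are independent across taxa before
renormalisation), classifier error and database incompleteness, cohort- or
nation-level batch structure, within-subject longitudinal correlation, and
age-dependent sequencing depth. Passing tests therefore demonstrate that
the statistical machinery recovers known structure of this kind — not that
the original cohort's specific counts (richness means, 104/45/9/36 screened
taxa, per-group core sizes 68/57/63, pseudo-F values) would be reproduced;
those depend on the real data and are deliberately out of scope.

# Numerical choices and degenerate inputs

* Permutation p-values use the add-one convention and a `−1e-12` slack on
  F/r² comparisons to make ties deterministic across platforms.
* PCoA drops eigenvalues below `1e-9 × max|λ|`; an all-zero distance matrix
  returns all-zero coordinates.
* All-zero samples: flagged by `to_relative()` (kept, as zero columns),
  rejected by Bray-Curtis and Shannon with typed errors.
* Taxa absent everywhere are skipped by the Spearman screen (reported in an
  attribute); taxa with zero variance get no ANOVA row; a table where
  every taxon is constant is a degenerate-input error.
* Compact-letter ties are broken by the group order of first appearance.
* Stage seeds derive from the global seed by a fixed 31-bit string hash of
  the stage name, so single stages can be reproduced independently.

# Problem sizes

The shipped analysis scripts simulate 250 samples per age group; the
acceptance checks use 500 per group for parameter recovery (binomial SE on
prevalence ≈ 2.2 points), 200 replicates for null-calibration checks, and
20 replicates for effect-sign recovery. These sizes give stable Monte-Carlo
behaviour at desk scale; all are parameters of the corresponding functions.

# Known limitations

* The compact-letter insertion algorithm can need more letters than groups
  in pathological non-transitive significance patterns; with four age
  groups this does not arise.
* The continent model assumes homoscedastic log-abundances; MaAsLin2's
  exact output will differ in detail (documented approximation, not a
  bit-compatible clone).
* Spearman p-values rely on the t approximation, which is anticonservative
  below ~10 samples; the pipeline is meant for cohort-scale data.
* The reference profile's two-decimal rounding limits boundary decisions —
  species within half a rounding unit of a threshold can legitimately flip.
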