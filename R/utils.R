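## Internal helpers shared across modules.

AGE_GROUPS <- c("G1", "G2", "G3", "G4")

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic 31-bit string hash used to fan a global seed out into
## independent per-stage seeds.
hash_string <- function(x) {
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Derive a per-stage seed from a global seed
#' @noRd
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + hash_string(stage)) %% 2147483647)
}

stop_agecore <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "agecore_error")))
}

assert_count_matrix <- function(counts, what = "count table") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_agecore(what, " must be a numeric matrix (taxa x samples)",
                 class = "agecore_format_error")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_agecore(what, " must carry taxon rownames and sample colnames",
                 class = "agecore_format_error")
  }
  if (anyDuplicated(rownames(counts))) {
    stop_agecore("duplicate taxon identifiers in ", what,
                 class = "agecore_format_error")
  }
  if (anyDuplicated(colnames(counts))) {
    stop_agecore("duplicate sample identifiers in ", what,
                 class = "agecore_format_error")
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop_agecore(what, " contains negative or missing values",
                 class = "agecore_format_error")
  }
  invisible(counts)
}

assert_integer_counts <- function(counts, what = "count table") {
  assert_count_matrix(counts, what)
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop_agecore(what, " must contain integer read counts",
                 class = "agecore_format_error")
  }
  invisible(counts)
}

## Benjamini-Hochberg adjustment; thin wrapper kept so every module corrects
## p-values the same way (NA-safe, preserves names).
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
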