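test_that("profile + metadata loading validates and aligns the two tables", {
  paths <- write_toy_tables()
  dat <- load_profile_table(paths$profile, paths$metadata)
  expect_equal(unname(colSums(dat$counts)), c(15, 25))
  expect_identical(dat$counts, toy_counts())
  expect_equal(dat$metadata$age_group, c("G1", "G3"))

  ## round trip is byte-identical on the count matrix
  p2 <- file.path(paths$dir, "again.tsv")
  write_profile_table(dat$counts, p2)
  expect_identical(readLines(p2), readLines(paths$profile))

  ## metadata missing a sample -> alignment error
  meta <- utils::read.delim(paths$metadata)
  utils::write.table(meta[1L, ], file.path(paths$dir, "short.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_profile_table(paths$profile,
                                  file.path(paths$dir, "short.tsv")),
               class = "agecore_alignment_error")

  ## duplicate taxon label -> format error
  lines <- readLines(paths$profile)
  writeLines(c(lines, lines[2L]), file.path(paths$dir, "dup.tsv"))
  expect_error(load_profile_table(file.path(paths$dir, "dup.tsv"),
                                  paths$metadata),
               class = "agecore_format_error")

  ## negative counts -> format error
  bad <- sub("^Genus two\t5\t5$", "Genus two\t-5\t5", lines)
  writeLines(bad, file.path(paths$dir, "neg.tsv"))
  expect_error(load_profile_table(file.path(paths$dir, "neg.tsv"),
                                  paths$metadata),
               class = "agecore_format_error")
})

test_that("subsampling caps over-depth samples exactly and leaves the rest", {
  set.seed(1)
  deep <- matrix(as.integer(rmultinom(1, 250000, prob = runif(40))),
                 ncol = 1, dimnames = list(sprintf("t%02d", 1:40), "deep"))
  shallow <- matrix(as.integer(rmultinom(1, 50000, prob = runif(40))),
                    ncol = 1, dimnames = list(sprintf("t%02d", 1:40), "shal"))
  counts <- cbind(deep, shallow)
  out <- subsample_reads(counts, cap = 100000, seed = 11)
  expect_identical(sum(out[, "deep"]), 100000L)
  expect_identical(out[, "shal"], counts[, "shal"])
  expect_true(all(out <= counts))
  ## determinism
  expect_identical(out, subsample_reads(counts, cap = 100000, seed = 11))
  expect_error(subsample_reads(counts, cap = 0),
               class = "agecore_parameter_error")
})

test_that("subsampling is unbiased for relative abundances", {
  x <- matrix(c(5000L, 2500L, 1500L, 800L, 200L), ncol = 1,
              dimnames = list(paste0("t", 1:5), "s"))
  p0 <- x[, 1] / sum(x)
  draws <- vapply(1:200, function(s) {
    subsample_reads(x, cap = 1000, seed = s)[, 1] / 1000
  }, numeric(5))
  est <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(200)
  expect_true(all(abs(est - p0) <= 3 * se + 1e-12))
})

test_that("WHO age groups are half-open, exhaustive and monotone", {
  expect_identical(assign_age_group(c(0.5, 17, 65, 4.9, 0, 5, 18, 64.99)),
                   c("G1", "G2", "G4", "G1", "G1", "G2", "G3", "G3"))
  ages <- sort(c(seq(0, 110, by = 0.37), 1 / 12, 0.5, 1, 5, 11, 18, 65))
  grp <- assign_age_group(ages)
  expect_false(anyNA(grp))
  expect_true(all(diff(match(grp, c("G1", "G2", "G3", "G4"))) >= 0))
  expect_error(assign_age_group(-1), class = "agecore_parameter_error")
})

test_that("early-life subgroups follow the month-resolved boundaries", {
  expect_identical(
    assign_age_subgroup(c(0.04, 0.75, 40, 0, 1 / 12, 0.5, 1, 5, 10.9, 11, 70)),
    c("G1a", "G1c", "G3", "G1a", "G1b", "G1c", "G1d", "G2a", "G2a", "G2",
      "G4"))
})

test_that("relative abundances normalise columns and flag empty samples", {
  m <- matrix(c(1L, 3L, 0L, 0L), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(rel <- to_relative(m), "all-zero")
  expect_equal(rel[, "s1"], c(a = 0.25, b = 0.75))
  expect_equal(unname(rel[, "s2"]), c(0, 0))
  expect_identical(attr(rel, "empty_samples"), "s2")
  one <- matrix(5L, 1, 1, dimnames = list("a", "s"))
  expect_equal(unname(to_relative(one)[1, 1]), 1)
})
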