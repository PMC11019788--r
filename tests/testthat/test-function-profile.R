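test_that("EC identifiers are validated and the registry has the key enzymes", {
  expect_true(all(is_valid_ec(c("3.2.1.23", "2.7.1.89", "1.1.1.-"))))
  expect_false(any(is_valid_ec(c("3.2.1", "a.b.c.d", "3..1.23", "3.2.1.23.5"))))
  reg <- key_enzyme_registry()
  expect_true(all(c("3.2.1.23", "2.7.1.89", "2.7.1.50", "3.6.1.27",
                    "2.7.1.23", "6.3.5.1") %in% reg$ec))
  expect_identical(reg$category[reg$ec == "3.2.1.23"], "lactose/HMO")
  ## user extension file
  f <- tempfile(fileext = ".tsv")
  writeLines("1.2.3.4\tfiber", f)
  expect_true("1.2.3.4" %in% key_enzyme_registry(f)$ec)
})

test_that("species-EC correlation finds constructed monotone links", {
  n <- 40
  set.seed(2)
  sp <- matrix(runif(2 * n, 0, 0.2), 2, n,
               dimnames = list(c("Linked species", "Other species"),
                               paste0("s", 1:n)))
  ec <- rbind("3.2.1.23" = sp["Linked species", ]^2,   # monotone transform
              "2.7.1.89" = runif(n))
  colnames(ec) <- colnames(sp)
  res <- species_ec_correlation(sp, ec)
  cell <- res[res$taxon == "Linked species" & res$ec == "3.2.1.23", ]
  expect_equal(cell$rho, 1)
  expect_true(cell$significant)
  ## registry ECs absent from the table are reported untested
  expect_true("2.7.1.50" %in% attr(res, "untested_ecs"))
  ## rank-based: uniform rescaling of the EC table is immaterial
  res2 <- species_ec_correlation(sp, ec * 3)
  expect_equal(res2$rho, res$rho)
})

test_that("independent EC vectors are masked after FDR in most replicates", {
  n <- 200
  masked <- vapply(1:50, function(r) {
    set.seed(1000 + r)
    sp <- matrix(rlnorm(3 * n), 3, n,
                 dimnames = list(c("A species", "B species", "C species"),
                                 paste0("s", 1:n)))
    ec <- matrix(runif(2 * n), 2, n,
                 dimnames = list(c("3.2.1.23", "2.7.1.23"), colnames(sp)))
    res <- species_ec_correlation(sp, ec, alpha = 0.05)
    !any(res$significant)
  }, logical(1))
  expect_gte(mean(masked), 0.86)
})

test_that("masking is monotone in alpha", {
  set.seed(14)
  n <- 60
  sp <- matrix(rlnorm(4 * n), 4, n,
               dimnames = list(paste0("Taxon ", letters[1:4]),
                               paste0("s", 1:n)))
  sp[1, ] <- sp[1, ] + seq_len(n) * 0.05
  ec <- rbind("3.2.1.23" = seq_len(n) + runif(n, 0, 20),
              "2.7.1.23" = runif(n))
  colnames(ec) <- colnames(sp)
  strict <- species_ec_correlation(sp, ec, alpha = 0.01)
  loose <- species_ec_correlation(sp, ec, alpha = 0.10)
  expect_true(all(which(strict$significant) %in% which(loose$significant)))
})

test_that("group summaries average signed correlations over group taxa", {
  corr <- data.frame(
    taxon = c("Infant sp", "Infant sp", "Adult sp"),
    ec = c("3.2.1.23", "2.7.1.89", "3.2.1.23"),
    category = c("lactose/HMO", "vitamin-thiamine", "lactose/HMO"),
    rho = c(0.8, 0.6, -0.5),
    p_value = 1e-4, q_value = 1e-3, significant = TRUE,
    rho_masked = c(0.8, 0.6, -0.5))
  cls <- data.frame(group = c("G1", "G3"),
                    taxon = c("Infant sp", "Adult sp"),
                    label = "core")
  sm <- group_enzyme_summary(corr, cls)
  expect_equal(sm$mean_rho[sm$group == "G1" & sm$category == "lactose/HMO"],
               0.8)
  expect_equal(sm$mean_rho[sm$group == "G3" & sm$category == "lactose/HMO"],
               -0.5)
  ## a group with no significant cell in a category gets NA
  expect_true(is.na(sm$mean_rho[sm$group == "G3" &
                                  sm$category == "vitamin-thiamine"]))
})

test_that("generator-linked enzymes surface as infancy-positive signals", {
  cfg <- default_synthetic_config(n_per_group = c(G1 = 100, G2 = 100,
                                                  G3 = 100, G4 = 100))
  ch <- generate_cohort(cfg, seed = 55)
  rel <- to_relative(ch$counts)
  taxa <- c("Bifidobacterium longum", "Escherichia coli",
            "Faecalibacterium prausnitzii", "Roseburia intestinalis")
  res <- species_ec_correlation(rel[taxa, ], ch$ec)
  cell <- res[res$taxon == "Bifidobacterium longum" & res$ec == "3.2.1.23", ]
  expect_true(cell$significant)
  expect_gt(cell$rho, 0)
})
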