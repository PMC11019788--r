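test_that("Spearman age screen recovers perfect monotone relationships", {
  n <- 20
  ages <- seq(0.5, 80, length.out = n)
  rel <- rbind(up = seq(0.01, 0.2, length.out = n),
               down = seq(0.2, 0.01, length.out = n),
               absent = rep(0, n))
  colnames(rel) <- paste0("s", 1:n)
  meta <- make_meta(colnames(rel), ages)
  res <- spearman_age_screen(rel, meta)
  expect_equal(res$rho[res$taxon == "up"], 1)
  expect_equal(res$rho[res$taxon == "down"], -1)
  expect_identical(attr(res, "skipped_taxa"), "absent")
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_identical(res$sign[res$taxon == "down"], "negative")
})

test_that("BH adjustment equals the hand step-up and a brute-force oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  set.seed(19)
  for (i in 1:100) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, method = "BH"), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("ANOVA + Tukey flags exactly the enriched groups", {
  n <- 30
  samples <- paste0("s", 1:(4 * n))
  ages <- rep(c(1, 10, 30, 70), each = n)
  meta <- make_meta(samples, ages)
  set.seed(4)
  noise <- rnorm(4 * n, 0.1, 0.01)
  shifted <- noise + rep(c(0.1, 0, 0, 0), each = n)  # 10 pooled SDs up in G1
  rel <- rbind(flat = rep(0.105, 4 * n),             # identical everywhere
               g1_up = pmin(pmax(shifted, 0), 1))
  colnames(rel) <- samples
  res <- anova_tukey_filter(rel, meta)
  expect_false(any(unlist(res[res$taxon == "flat",
                              paste0("flag_", c("G1", "G2", "G3", "G4"))])))
  expect_true(res$flag_G1[res$taxon == "g1_up"])
  expect_false(res$flag_G3[res$taxon == "g1_up"])

  same <- rbind(const = rep(0.2, 4 * n))
  colnames(same) <- samples
  expect_error(anova_tukey_filter(same, meta),
               class = "agecore_degenerate_error")
})

test_that("Tukey HSD at two groups reduces to the pooled t-test", {
  set.seed(6)
  y <- c(rnorm(12, 0), rnorm(15, 0.8))
  g <- factor(rep(c("a", "b"), c(12, 15)))
  tk <- TukeyHSD(aov(y ~ g))$g
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(unname(tk[, "p adj"]), tt$p.value, tolerance = 1e-9)
})

test_that("the two-stage selection recovers the planted sign partition", {
  set.seed(23)
  n <- 200                       # per group
  samples <- paste0("s", 1:(4 * n))
  ages <- c(runif(n, 0, 5), runif(n, 5, 18), runif(n, 18, 65),
            runif(n, 65, 95))
  meta <- make_meta(samples, ages)
  lognorm <- function(mu) rlnorm(4 * n, log(mu), 0.4)
  mk <- function(mult) {       # per-group fold pattern, length 4
    base <- 0.01 * rep(mult, each = n)
    base * rlnorm(4 * n, 0, 0.4)
  }
  rel <- rbind(
    do.call(rbind, lapply(1:5, function(i) mk(c(4, 1, 1, 1)))),   # infant
    do.call(rbind, lapply(1:10, function(i) mk(c(1, 4, 4, 4)))),  # adult
    do.call(rbind, lapply(1:6, function(i) mk(c(1, 1, 1, 1))))    # null
  )
  rownames(rel) <- c(paste0("infant_", 1:5), paste0("adult_", 1:10),
                     paste0("null_", 1:6))
  colnames(rel) <- samples
  s1 <- spearman_age_screen(rel, meta)
  s2 <- anova_tukey_filter(rel, meta)
  sel <- select_age_associated(s1, s2)
  expect_setequal(sel$negative_with_age, paste0("infant_", 1:5))
  expect_setequal(sel$positive_with_age, paste0("adult_", 1:10))
  ## sign partition consistency
  res <- sel$results
  expect_true(all(res$rho[res$taxon %in% sel$negative_with_age] < 0))
  expect_true(all(res$rho[res$taxon %in% sel$positive_with_age] > 0))
})

test_that("selection is the conjunction of both stages", {
  s1 <- data.frame(taxon = c("a", "b"), rho = c(0.4, 0.5),
                   p_value = c(0.001, 0.5), q_value = c(0.002, 0.5),
                   pass_stage1 = c(TRUE, FALSE),
                   sign = c("positive", "positive"))
  s2 <- data.frame(taxon = c("a", "b"), anova_p = c(0.5, 0.001),
                   flag_G1 = c(FALSE, TRUE), any_flag = c(FALSE, TRUE))
  sel <- select_age_associated(s1, s2)
  expect_length(sel$positive_with_age, 0)
  expect_length(sel$negative_with_age, 0)
  expect_false(any(sel$results$selected))
})
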