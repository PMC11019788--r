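test_that("richness and Shannon follow their definitions", {
  expect_identical(richness(c(3, 0, 1, 0)), 2L)
  expect_identical(richness(c(0, 0)), 0L)
  expect_equal(shannon(rep(1, 10)), log(10))
  expect_equal(shannon(c(0, 7, 0)), 0)
  expect_equal(shannon(c(1, 1, 2)), 1.039721, tolerance = 1e-6)
  expect_error(shannon(c(0, 0)), class = "agecore_degenerate_error")
})

test_that("Bray-Curtis matches its formula, range and invariances", {
  m <- matrix(c(2, 2, 2, 0), nrow = 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  d <- bray_curtis(m)
  expect_equal(d["x", "y"], 1 / 3)
  same <- matrix(c(1, 2, 1, 2), nrow = 2,
                 dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(bray_curtis(same)["x", "y"], 0)
  disj <- matrix(c(3, 0, 0, 5), nrow = 2,
                 dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(bray_curtis(disj)["x", "y"], 1)

  set.seed(42)
  X <- matrix(rpois(15 * 8, 6), 15, 8,
              dimnames = list(paste0("t", 1:15), paste0("s", 1:8)))
  D <- bray_curtis(X)
  expect_equal(D, t(D))
  expect_true(all(D >= 0 & D <= 1))
  ## joint rescaling of all samples leaves the dissimilarity unchanged
  expect_equal(bray_curtis(X * 7), D)
  ## independent oracle: vegan's vegdist
  skip_if_not_installed("vegan")
  Dv <- as.matrix(vegan::vegdist(t(X), method = "bray"))
  expect_equal(unname(D), unname(Dv), tolerance = 1e-12)
  zero <- cbind(X[, 1, drop = FALSE], none = 0L)
  expect_error(bray_curtis(zero), class = "agecore_degenerate_error")
})

test_that("PCoA reproduces Euclidean geometry and handles degenerate input", {
  ## three mutually equidistant points: two equal positive eigenvalues
  D3 <- matrix(1, 3, 3) - diag(3)
  o3 <- agecore::pcoa(D3, k = 2)
  expect_length(o3$eigenvalues, 2L)
  expect_equal(o3$eigenvalues[1], o3$eigenvalues[2])
  expect_true(all(o3$eigenvalues > 0))

  ## collinear points: axis 1 recovers the order up to sign
  pts <- c(0, 1, 3, 7)
  D4 <- as.matrix(dist(pts))
  o4 <- agecore::pcoa(D4, k = 3)
  ax1 <- o4$coordinates[, 1]
  expect_true(all(diff(ax1) > 0) || all(diff(ax1) < 0))

  ## Euclidean input: retained coordinates reproduce all pairwise distances
  set.seed(3)
  P <- matrix(rnorm(10 * 3), 10, 3)
  De <- as.matrix(dist(P))
  rownames(De) <- colnames(De) <- paste0("s", 1:10)
  oe <- agecore::pcoa(De, k = 9)
  expect_lt(max(abs(as.matrix(dist(oe$coordinates)) - De)), 1e-8)
  expect_true(all(diff(oe$eigenvalues) <= 1e-9))
  expect_lte(sum(oe$proportion_explained), 1 + 1e-12)

  ## independent oracle: ape's classical scaling eigenvalues
  skip_if_not_installed("ape")
  oa <- ape::pcoa(De)
  expect_equal(oe$eigenvalues,
               oa$values$Eigenvalues[seq_along(oe$eigenvalues)],
               tolerance = 1e-8)

  z <- matrix(0, 4, 4)
  oz <- agecore::pcoa(z, k = 2)
  expect_true(all(oz$coordinates == 0))
  expect_error(agecore::pcoa(D3, k = 0), class = "agecore_parameter_error")
})

test_that("pairwise Kruskal-Wallis letters separate exactly the significant pairs", {
  set.seed(11)
  pool <- rnorm(60)
  same <- pairwise_kruskal(pool, rep(c("u", "v"), 30))
  expect_identical(unname(same$letters["u"]), unname(same$letters["v"]))

  vals <- c(rnorm(50, 0), rnorm(50, 5), rnorm(50, 0))
  grp <- rep(c("lo1", "hi", "lo2"), each = 50)
  cld <- pairwise_kruskal(vals, grp, alpha = 0.05)
  expect_false(grepl(cld$letters["hi"], cld$letters["lo1"], fixed = TRUE))
  ## groups sharing a letter are exactly the non-significant pairs
  shares <- function(a, b) {
    any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
  }
  for (pair in list(c("lo1", "hi"), c("lo1", "lo2"), c("hi", "lo2"))) {
    expect_identical(shares(cld$letters[pair[1]], cld$letters[pair[2]]),
                     cld$p_matrix[pair[1], pair[2]] >= 0.05)
  }

  ## exact rank case: 1..6 vs 7..12 is significant below 0.01
  r <- pairwise_kruskal(1:12, rep(c("a", "b"), each = 6))
  expect_lt(r$p_matrix["a", "b"], 0.01)
  expect_error(pairwise_kruskal(1:3, c("a", "a", "b")),
               class = "agecore_parameter_error")
})

test_that("PERMANOVA matches adonis2 and its exhaustive enumeration", {
  set.seed(5)
  X <- matrix(rpois(12 * 6, 10), 12, 6,
              dimnames = list(paste0("t", 1:12), paste0("s", 1:6)))
  D <- bray_curtis(to_relative(X))
  g <- rep(c("a", "b"), each = 3)

  skip_if_not_installed("vegan")
  fit <- permanova(D, g, n_perm = 999, seed = 2)
  ref <- vegan::adonis2(as.dist(D) ~ g, permutations = 999)
  expect_equal(fit$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(fit$R2, ref$R2[1], tolerance = 1e-10)

  ## exhaustive p equals a brute-force enumeration with adonis2 as the
  ## F oracle on every relabelling
  ex <- permanova(D, g, n_perm = "exhaustive")
  perms <- agecore:::all_permutations(6L)
  fs <- apply(perms, 1, function(ix) {
    vegan::adonis2(as.dist(D) ~ gg, permutations = 2,
                   data = data.frame(gg = g[ix]))$F[1]
  })
  expect_equal(ex$p_value, mean(fs >= fit$pseudo_F - 1e-12))
})

test_that("PERMANOVA separates distinct clouds at the minimal attainable p", {
  set.seed(8)
  pts <- rbind(matrix(rnorm(24, 0, 0.2), 12), matrix(rnorm(24, 5, 0.2), 12))
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- paste0("s", 1:24)
  fit <- permanova(D, rep(c("a", "b"), each = 12), n_perm = 999, seed = 4)
  expect_equal(fit$p_value, 1 / 1000)
  expect_error(permanova(D, c("a", rep("b", 23))),
               class = "agecore_parameter_error")
})

test_that("pairwise PERMANOVA q-values keep the BH monotonicity", {
  cfg <- default_synthetic_config(n_per_group = c(G1 = 15, G2 = 15,
                                                  G3 = 15, G4 = 15))
  ch <- generate_cohort(cfg, seed = 12)
  D <- bray_curtis(to_relative(ch$counts))
  pw <- pairwise_permanova(D, ch$metadata$age_group, n_perm = 99, seed = 3)
  expect_identical(nrow(pw), 6L)
  o <- order(pw$p_value)
  expect_true(all(diff(pw$q_value[o]) >= -1e-12))
  expect_true(all(pw$q_value >= pw$p_value - 1e-12))
})

test_that("envfit-style fitting matches the algebra and vegan", {
  set.seed(9)
  X <- matrix(rpois(20 * 25, 7), 20, 25,
              dimnames = list(paste0("t", 1:20), paste0("s", 1:25)))
  ord <- agecore::pcoa(bray_curtis(to_relative(X)), k = 2)

  ## perfect fit: the variable IS axis 1
  perfect <- envfit_ord(ord, data.frame(v = ord$coordinates[, 1]),
                        n_perm = 99, seed = 1)
  expect_equal(perfect$r_squared, 1, tolerance = 1e-12)

  ## algebraic oracle on a 5-sample toy: direct normal equations
  co <- ord$coordinates[1:5, ]
  y <- c(0.3, -1, 2, 0.5, -0.2)
  f5 <- envfit_ord(co, data.frame(y = y), n_perm = 99, seed = 1)
  Xc <- scale(co, scale = FALSE)
  yc <- y - mean(y)
  beta <- solve(t(Xc) %*% Xc, t(Xc) %*% yc)
  r2_direct <- sum((Xc %*% beta)^2) / sum(yc^2)
  expect_equal(f5$r_squared, r2_direct, tolerance = 1e-10)

  skip_if_not_installed("vegan")
  v <- rnorm(25)
  mine <- envfit_ord(ord, data.frame(v = v), n_perm = 199, seed = 7)
  ref <- vegan::envfit(ord$coordinates, data.frame(v = v), permutations = 199)
  expect_equal(mine$r_squared, unname(ref$vectors$r), tolerance = 1e-10)
  expect_equal(abs(c(mine$dir_1, mine$dir_2)),
               abs(as.numeric(ref$vectors$arrows)), tolerance = 1e-8)

  const <- envfit_ord(ord, data.frame(k = rep(1, 25)), n_perm = 99, seed = 1)
  expect_true(const$degenerate)
  expect_true(is.na(const$r_squared))
})
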