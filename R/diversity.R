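#' Species richness per sample
#'
#' Number of taxa with a positive count (or abundance).
#' @param x Numeric vector (one sample) or taxa x samples matrix.
#' @return Integer, or named integer vector for a matrix.
#' @export
richness <- function(x) {
  if (is.matrix(x)) return(colSums(x > 0))
  if (anyNA(x) || any(x < 0)) {
    stop_agecore("counts must be non-negative", class = "agecore_parameter_error")
  }
  sum(x > 0)
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over taxa with positive proportion `p_i`,
#' natural logarithm by default.
#' @param x Numeric vector (one sample) or taxa x samples matrix.
#' @param base Logarithm base (default `exp(1)`).
#' @return Numeric `>= 0`.
#' @export
shannon <- function(x, base = exp(1)) {
  if (is.matrix(x)) return(apply(x, 2L, shannon, base = base))
  if (anyNA(x) || any(x < 0)) {
    stop_agecore("counts must be non-negative", class = "agecore_parameter_error")
  }
  total <- sum(x)
  if (total == 0) {
    stop_agecore("Shannon index undefined for an all-zero sample",
                 class = "agecore_degenerate_error")
  }
  p <- x[x > 0] / total
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = 1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`, equivalently
#' `sum(|x - y|) / (sum(x) + sum(y))`, computed between all sample pairs of an
#' aligned abundance matrix; values lie in `[0, 1]`.
#'
#' @param rel Taxa x samples matrix (relative abundances recommended so
#'   depth-capped samples are comparable).
#' @return Symmetric sample x sample matrix with zero diagonal.
#' @export
bray_curtis <- function(rel) {
  assert_count_matrix(rel, "abundance table")
  totals <- colSums(rel)
  if (any(totals == 0)) {
    stop_agecore("Bray-Curtis undefined for all-zero sample(s): ",
                 paste(colnames(rel)[totals == 0], collapse = ", "),
                 class = "agecore_degenerate_error")
  }
  num <- as.matrix(stats::dist(t(rel), method = "manhattan"))
  den <- outer(totals, totals, "+")
  d <- num / den
  dimnames(d) <- list(colnames(rel), colnames(rel))
  diag(d) <- 0
  d
}

#' Principal coordinate analysis
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues. Negative eigenvalues are dropped, with their total magnitude
#' reported; no Lingoes/Cailliez correction is applied.
#'
#' @param D Symmetric distance matrix.
#' @param k Number of axes to retain (capped at the positive-eigenvalue count).
#' @return List of class `agecore_pcoa`: `coordinates` (n x k'),
#'   `eigenvalues` (retained, non-increasing), `proportion_explained`,
#'   `negative_eigenvalue_magnitude`, `correction_applied = FALSE`.
#' @export
pcoa <- function(D, k = 2L) {
  D <- as.matrix(D)
  if (k < 1) stop_agecore("k must be >= 1", class = "agecore_parameter_error")
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-12) {
    stop_agecore("D must be a symmetric matrix", class = "agecore_format_error")
  }
  n <- nrow(D)
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1L, rowMeans(A)), 2L, colMeans(A)) + mean(A)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values), 1e-300) * 1e-9
  pos <- which(e$values > tol)
  neg_mag <- sum(abs(e$values[e$values < -tol]))
  if (!length(pos)) {
    coords <- matrix(0, n, min(k, n - 1L))
    rownames(coords) <- rownames(D)
    return(structure(list(coordinates = coords, eigenvalues = numeric(),
                          proportion_explained = numeric(),
                          negative_eigenvalue_magnitude = neg_mag,
                          correction_applied = FALSE),
                     class = "agecore_pcoa"))
  }
  keep <- pos[seq_len(min(k, length(pos)))]
  ev <- e$values[keep]
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev), length(keep))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("Axis", seq_along(keep))
  structure(list(coordinates = coords, eigenvalues = ev,
                 proportion_explained = ev / sum(e$values[pos]),
                 negative_eigenvalue_magnitude = neg_mag,
                 correction_applied = FALSE),
            class = "agecore_pcoa")
}

#' Pairwise Kruskal-Wallis tests with a compact letter display
#'
#' Runs the (tie-corrected) Kruskal-Wallis rank test on every group pair and
#' summarises the pattern with compact letters assigned by the insertion
#' algorithm: two groups share a letter exactly when their pairwise test is
#' non-significant at `alpha`. P-values are raw per pair by default
#' (`p_adjust = "none"`); set `p_adjust = "BH"` for FDR-corrected letters.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation (`>= 2` groups, each `n >= 2`).
#' @param alpha Significance level for the letters.
#' @param p_adjust Multiplicity correction across pairs.
#' @return List of class `agecore_cld`: `letters` (named character vector, tie
#'   order follows the group factor order) and `p_matrix`.
#' @export
pairwise_kruskal <- function(values, groups, alpha = 0.05,
                             p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  groups <- as.character(groups)
  lev <- unique(groups)
  sizes <- table(groups)
  if (length(lev) < 2L || any(sizes < 2L)) {
    stop_agecore(">=2 groups with >=2 observations each required",
                 class = "agecore_parameter_error")
  }
  P <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  pairs <- utils::combn(lev, 2L)
  pvals <- apply(pairs, 2L, function(pr) {
    sel <- groups %in% pr
    stats::kruskal.test(values[sel], factor(groups[sel]))$p.value
  })
  if (p_adjust == "BH") pvals <- bh_adjust(pvals)
  for (i in seq_len(ncol(pairs))) {
    P[pairs[1L, i], pairs[2L, i]] <- pvals[i]
    P[pairs[2L, i], pairs[1L, i]] <- pvals[i]
  }
  diag(P) <- 1
  structure(list(letters = compact_letters(P < alpha, lev), p_matrix = P),
            class = "agecore_cld")
}

## Insertion algorithm for compact letter displays (Piepho-style): start from
## one column holding every group; each significant pair splits any column
## containing both; absorb columns that became subsets of others.
compact_letters <- function(sig, lev) {
  cols <- list(lev)
  pairs <- which(sig & upper.tri(sig), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    a <- lev[pairs[r, 1L]]
    b <- lev[pairs[r, 2L]]
    new_cols <- list()
    for (col in cols) {
      if (all(c(a, b) %in% col)) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    ## absorption: drop any column contained in another
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) {
      for (j in seq_along(new_cols)) {
        if (i != j && keep[j] && all(new_cols[[i]] %in% new_cols[[j]]) &&
            (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j)) {
          keep[i] <- FALSE
          break
        }
      }
    }
    cols <- new_cols[keep]
  }
  lab <- vapply(lev, function(g) {
    paste0(letters[which(vapply(cols, function(col) g %in% col, logical(1L)))],
           collapse = "")
  }, character(1L))
  names(lab) <- lev
  lab
}

permanova_ss <- function(D2, labels) {
  n <- nrow(D2)
  lev <- unique(labels)
  ss_total <- sum(D2) / (2 * n)
  ss_within <- 0
  for (g in lev) {
    idx <- which(labels == g)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  k <- length(lev)
  ss_between <- ss_total - ss_within
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  c(F = f, R2 = ss_between / ss_total)
}

#' PERMANOVA on a distance matrix
#'
#' Pseudo-F from within/between sums of squared distances
#' (`SS_total = sum_{i<j} d_ij^2 / n`, `SS_within` summed per group), tested
#' by label permutation with the add-one convention
#' `p = (1 + #permuted F >= observed) / (n_perm + 1)`, so p is never zero and
#' the minimal attainable p is `1/(n_perm + 1)`. With
#' `n_perm = "exhaustive"` every permutation of the labels is enumerated
#' (feasible for small n) and p is the exact proportion with `F >= observed`.
#'
#' @param D Symmetric distance matrix.
#' @param labels Group label per sample (every group `n >= 2`).
#' @param n_perm Number of permutations (default 999) or `"exhaustive"`.
#' @param seed Integer seed for the permutations.
#' @return List of class `agecore_permanova`: `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations`.
#' @export
permanova <- function(D, labels, n_perm = 999L, seed = 1L) {
  D <- as.matrix(D)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(D))
  if (any(table(labels) < 2L) || length(unique(labels)) < 2L) {
    stop_agecore("every group needs >= 2 samples and >= 2 groups",
                 class = "agecore_parameter_error")
  }
  D2 <- D^2
  obs <- permanova_ss(D2, labels)
  if (identical(n_perm, "exhaustive")) {
    perms <- all_permutations(length(labels))
    fs <- apply(perms, 1L, function(ix) permanova_ss(D2, labels[ix])[["F"]])
    p <- mean(fs >= obs[["F"]] - 1e-12)
    np <- nrow(perms)
  } else {
    fs <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        permanova_ss(D2, sample(labels))[["F"]]
      }, numeric(1L))
    })
    p <- (1 + sum(fs >= obs[["F"]] - 1e-12)) / (n_perm + 1)
    np <- as.integer(n_perm)
  }
  structure(list(pseudo_F = obs[["F"]], R2 = obs[["R2"]], p_value = p,
                 n_permutations = np),
            class = "agecore_permanova")
}

all_permutations <- function(n) {
  if (n > 9L) {
    stop_agecore("exhaustive enumeration limited to n <= 9",
                 class = "agecore_parameter_error")
  }
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Pairwise PERMANOVA with BH-adjusted q-values
#'
#' Runs [permanova()] on every group pair and adjusts the p-values across
#' pairs with Benjamini-Hochberg.
#' @inheritParams permanova
#' @return data.frame: `group1`, `group2`, `pseudo_F`, `R2`, `p_value`,
#'   `q_value`.
#' @export
pairwise_permanova <- function(D, labels, n_perm = 999L, seed = 1L) {
  D <- as.matrix(D)
  labels <- as.character(labels)
  lev <- unique(labels)
  pairs <- utils::combn(lev, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    sel <- labels %in% pairs[, i]
    fit <- permanova(D[sel, sel, drop = FALSE], labels[sel], n_perm = n_perm,
                     seed = stage_seed(seed, paste(pairs[, i], collapse = "-")))
    data.frame(group1 = pairs[1L, i], group2 = pairs[2L, i],
               pseudo_F = fit$pseudo_F, R2 = fit$R2, p_value = fit$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_adjust(out$p_value)
  out
}

#' Fit external variables onto an ordination (envfit-style)
#'
#' Least-squares regression of each centered variable on the ordination axes:
#' `r^2 = 1 - RSS/TSS`, direction is the unit vector of regression
#' coefficients, and significance comes from permuting the variable across
#' samples (add-one convention).
#'
#' @param ord An `agecore_pcoa` (or any matrix of sample coordinates).
#' @param variables data.frame or matrix of per-sample numeric variables.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param choices Ordination axes used (default first two).
#' @return data.frame: `variable`, `r_squared`, `p_value`, plus unit-direction
#'   columns `dir_1..dir_k`; constant variables get `NA` with a note in the
#'   `degenerate` column.
#' @export
envfit_ord <- function(ord, variables, n_perm = 999L, seed = 1L,
                       choices = 1:2) {
  coords <- if (inherits(ord, "agecore_pcoa")) ord$coordinates else as.matrix(ord)
  choices <- choices[choices <= ncol(coords)]
  if (length(choices) < 2L) {
    stop_agecore("ordination needs >= 2 axes", class = "agecore_parameter_error")
  }
  X <- scale(coords[, choices, drop = FALSE], center = TRUE, scale = FALSE)
  XtXi <- solve(crossprod(X))
  variables <- as.data.frame(variables)
  res <- lapply(names(variables), function(v) {
    y <- as.numeric(variables[[v]])
    stopifnot(length(y) == nrow(X))
    yc <- y - mean(y)
    tss <- sum(yc^2)
    dirn <- rep(NA_real_, length(choices))
    if (tss < 1e-300) {
      row <- data.frame(variable = v, r_squared = NA_real_,
                        p_value = NA_real_, degenerate = TRUE)
    } else {
      r2_of <- function(yy) {
        b <- XtXi %*% crossprod(X, yy)
        sum((X %*% b)^2) / sum(yy^2)
      }
      r2 <- r2_of(yc)
      b <- XtXi %*% crossprod(X, yc)
      dirn <- as.numeric(b / sqrt(sum(b^2)))
      perm_r2 <- with_seed(stage_seed(seed, v), {
        vapply(seq_len(n_perm), function(i) {
          yp <- sample(yc)
          r2_of(yp - mean(yp))
        }, numeric(1L))
      })
      p <- (1 + sum(perm_r2 >= r2 - 1e-12)) / (n_perm + 1)
      row <- data.frame(variable = v, r_squared = r2, p_value = p,
                        degenerate = FALSE)
    }
    for (i in seq_along(choices)) row[[paste0("dir_", i)]] <- dirn[i]
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
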