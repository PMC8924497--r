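#' Standardized regression coefficient of a single-predictor model
#'
#' Ordinary least squares of `y` on `x` with intercept; the standardized
#' coefficient (SRC) is the slope times sd(x)/sd(y), which for a single
#' predictor equals the Pearson correlation. The p value is the two-sided
#' t test of the slope. A response with zero variance (e.g. a strategy
#' group absent from every plot) yields a flagged "no variance" result
#' rather than an error.
#'
#' @param y Numeric response (e.g. a group's plot-level proportions).
#' @param x Numeric predictor.
#' @param group,predictor Optional labels carried into the result.
#' @param covariates Optional data.frame of adjustment covariates (e.g. a
#'   site factor); the SRC is then the standardized partial slope of `x`.
#' @return One-row data.frame: `group`, `predictor`, `src`, `p_value`, `n`,
#'   `note`.
#' @export
src_regression <- function(y, x, group = NA_character_,
                           predictor = NA_character_, covariates = NULL) {
  ok <- stats::complete.cases(y, x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("predictor is constant", call. = FALSE)
  if (stats::sd(y) == 0) {
    return(data.frame(group = group, predictor = predictor, src = NA_real_,
                      p_value = NA_real_, n = n, note = "no variance",
                      stringsAsFactors = FALSE))
  }
  dat <- data.frame(.y = y, .x = x)
  if (!is.null(covariates)) dat <- cbind(dat, covariates[ok, , drop = FALSE])
  fit <- stats::lm(.y ~ ., data = dat)
  sm <- summary(fit)$coefficients
  data.frame(group = group, predictor = predictor,
             src = unname(sm[".x", "Estimate"]) * stats::sd(x) / stats::sd(y),
             p_value = unname(sm[".x", "Pr(>|t|)"]),
             n = n, note = "", stringsAsFactors = FALSE)
}

#' SRC models for every strategy group and diversity index
#'
#' Fits the 4 x 3 grid of single-predictor linear models relating each
#' group's plot-level proportion (`p_c`, `p_s`, `p_r`, `p_int`) to each
#' diversity index (richness, abundance, Shannon), reporting standardized
#' regression coefficients and slope p values. `adjust_site = TRUE` adds
#' the site (forest type) as a fixed-effect covariate, so the SRC reflects
#' the within-site association.
#'
#' @param spectra Plot-level spectrum table from [plot_spectra()].
#' @param div Diversity table from [diversity_indices()].
#' @param adjust_site Adjust for site as a fixed effect (requires a
#'   `site_id` column in `div`).
#' @return data.frame of 12 [src_regression()] rows.
#' @export
group_diversity_models <- function(spectra, div, adjust_site = FALSE) {
  dat <- merge(spectra, div, by.x = "unit_id", by.y = "plot_id")
  if (nrow(dat) < 3) stop("fewer than 3 plots after alignment", call. = FALSE)
  covs <- NULL
  if (adjust_site) {
    if (is.null(dat$site_id)) stop("adjust_site needs div$site_id", call. = FALSE)
    covs <- data.frame(site = factor(dat$site_id))
  }
  grid <- expand.grid(group = .group_levels,
                      predictor = c("richness", "abundance", "shannon"),
                      stringsAsFactors = FALSE)
  resp <- c("C-group" = "p_c", "S-group" = "p_s", "R-group" = "p_r",
            "Int-group" = "p_int")
  out <- lapply(seq_len(nrow(grid)), function(i) {
    src_regression(dat[[resp[[grid$group[i]]]]], dat[[grid$predictor[i]]],
                   group = grid$group[i], predictor = grid$predictor[i],
                   covariates = covs)
  })
  do.call(rbind, out)
}

.anova_f <- function(values, labels) {
  # one-way F by explicit sums of squares
  grand <- mean(values)
  ns <- tapply(values, labels, length)
  means <- tapply(values, labels, mean)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[labels])^2)
  k <- length(ns)
  (ssb / (k - 1)) / (ssw / (length(values) - k))
}

#' Permutation test for differences among group-proportion distributions
#'
#' Stacks the four plot-level group proportions into a one-way layout
#' (4 x n observations) and tests the one-way ANOVA F statistic against
#' its permutation distribution under random reshuffling of group labels.
#'
#' @param spectra Plot-level spectrum table.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @return list with `f_stat`, `p_perm`, `n_perm`, `n`.
#' @export
compare_group_proportions <- function(spectra, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- c(spectra$p_c, spectra$p_s, spectra$p_r, spectra$p_int)
  labs <- factor(rep(c("C", "S", "R", "Int"), each = nrow(spectra)))
  if (stats::sd(vals) == 0) stop("no variance among proportions", call. = FALSE)
  f_obs <- .anova_f(vals, labs)
  hits <- sum(vapply(seq_len(n_perm), function(i) {
    .anova_f(vals, sample(labs))
  }, numeric(1)) >= f_obs)
  list(f_stat = f_obs, p_perm = (1 + hits) / (1 + n_perm),
       n_perm = n_perm, n = nrow(spectra))
}

#' Hellinger transformation of a composition matrix
#'
#' Cell (i, j) becomes sqrt(y_ij / row total i) (via
#' [vegan::decostand()]), so each transformed row has unit sum of squares;
#' Euclidean distances on the result are Hellinger distances, making the
#' matrix suitable for RDA.
#'
#' @param m Non-negative matrix (or spectrum table columns) with positive
#'   row sums.
#' @return Transformed numeric matrix.
#' @export
hellinger <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("composition values must be non-negative", call. = FALSE)
  if (any(rowSums(m) <= 0)) stop("row sums must be positive", call. = FALSE)
  out <- vegan::decostand(m, method = "hellinger")
  attr(out, "decostand") <- NULL
  attr(out, "parameters") <- NULL
  out
}

#' Ezekiel-adjusted R squared
#'
#' adj-R2 = 1 - (1 - R2) (n - 1) / (n - k - 1), the convention of the
#' standard RDA implementations.
#'
#' @param r2 Unadjusted R squared.
#' @param n Number of observations.
#' @param k Number of predictor columns.
#' @return Adjusted R squared (may be negative).
#' @export
adjusted_r2 <- function(r2, n, k) {
  if (n <= k + 1) stop("need n > k + 1", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

.rda_r2 <- function(Xs, Yc, ss_tot) {
  b <- solve(crossprod(Xs), crossprod(Xs, Yc))
  sum((Xs %*% b)^2) / ss_tot
}

#' Redundancy analysis with a Monte Carlo permutation test
#'
#' Classical RDA: the response matrix is column-centered, the predictors
#' z-scored, and the fitted values of the multivariate least-squares
#' regression Yhat = X (X'X)^-1 X' Y are decomposed by SVD. Constrained
#' eigenvalues are the squared singular values of Yhat / (n - 1); residual
#' eigenvalues come from Y - Yhat; their sum equals the total variance of
#' the centered response. R2 = constrained / total variance,
#' F = (R2 / k) / ((1 - R2) / (n - k - 1)), and the permutation p value is
#' (1 + #\{F_perm >= F_obs\}) / (1 + n_perm) under unrestricted row
#' permutation of the predictors.
#'
#' Score conventions: site scores are the plot coordinates on the
#' constrained axes (linear-combination scores, scaled by the singular
#' values / sqrt(n - 1)), response scores are the right singular vectors,
#' and predictor scores the correlations of the z-scored predictors with
#' the site scores.
#'
#' @param Y Response matrix (e.g. Hellinger-transformed spectra).
#' @param X Predictor matrix or data.frame (n rows, k < n columns).
#' @param n_perm Number of permutations (0 skips the test).
#' @param seed Optional integer seed for the permutations.
#' @return Object of class `csr_rda`: eigenvalues, `r2`, `adj_r2`,
#'   `f_stat`, `p_perm`, per-axis percentages of total and of constrained
#'   variance, and the three score tables.
#' @export
csr_rda <- function(Y, X, n_perm = 999, seed = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y); k <- ncol(X)
  if (nrow(X) != n) stop("Y and X must have the same rows", call. = FALSE)
  if (n <= k + 1) stop("need n > k + 1 observations", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xs <- scale(X, center = TRUE, scale = TRUE)
  if (any(!is.finite(Xs))) stop("constant predictor column", call. = FALSE)
  xtx <- crossprod(Xs)
  if (rcond(xtx) < 1e-12) {
    stop("predictors are collinear (singular X'X); screen with vif() first",
         call. = FALSE)
  }
  ss_tot <- sum(Yc^2)
  Yhat <- Xs %*% solve(xtx, crossprod(Xs, Yc))
  sv <- svd(Yhat)
  nax <- min(k, ncol(Y), n - 1)
  eig_c <- (sv$d^2 / (n - 1))[seq_len(nax)]
  sv_res <- svd(Yc - Yhat)
  eig_r <- sv_res$d^2 / (n - 1)
  eig_r <- eig_r[eig_r > max(1e-12 * sum(eig_r), 1e-14)]
  total <- ss_tot / (n - 1)
  r2 <- min(sum(eig_c) / total, 1)
  # a numerically perfect fit has F = +Inf rather than a sign-flipped ratio
  f_of_r2 <- function(r2) {
    ifelse(1 - r2 < 1e-14, Inf, (r2 / k) / ((1 - r2) / (n - k - 1)))
  }
  f_stat <- f_of_r2(r2)
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    r2_perm <- vapply(seq_len(n_perm), function(i) {
      .rda_r2(Xs[sample(n), , drop = FALSE], Yc, ss_tot)
    }, numeric(1))
    p_perm <- (1 + sum(f_of_r2(pmin(r2_perm, 1)) >= f_stat)) / (1 + n_perm)
  }
  axes <- paste0("RDA", seq_len(nax))
  site_scores <- sv$u[, seq_len(nax), drop = FALSE] %*%
    diag(sv$d[seq_len(nax)], nax) / sqrt(n - 1)
  dimnames(site_scores) <- list(rownames(Y), axes)
  response_scores <- sv$v[, seq_len(nax), drop = FALSE]
  dimnames(response_scores) <- list(colnames(Y), axes)
  predictor_scores <- suppressWarnings(stats::cor(Xs, site_scores))
  structure(list(
    eig_constrained = stats::setNames(eig_c, axes),
    eig_residual = eig_r,
    total_variance = total,
    r2 = r2,
    adj_r2 = adjusted_r2(r2, n, k),
    f_stat = f_stat,
    p_perm = p_perm,
    axis_pct_total = stats::setNames(100 * eig_c / total, axes),
    axis_pct_constrained = stats::setNames(100 * eig_c / sum(eig_c), axes),
    site_scores = site_scores,
    response_scores = response_scores,
    predictor_scores = predictor_scores,
    n = n, k = k, n_perm = n_perm
  ), class = "csr_rda")
}

#' @export
print.csr_rda <- function(x, ...) {
  cat(sprintf("RDA: n = %d plots, k = %d predictors\n", x$n, x$k))
  cat(sprintf("  R2 = %.4f, adj-R2 = %.4f, F = %.2f, permutation P = %s (%d perms)\n",
              x$r2, x$adj_r2, x$f_stat,
              ifelse(is.na(x$p_perm), "not run", format(x$p_perm)), x$n_perm))
  cat("  axis % of total variance: ",
      paste(sprintf("%s %.2f%%", names(x$axis_pct_total), x$axis_pct_total),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Retain predictors significant in marginal RDA permutation tests
#'
#' Fits one single-predictor RDA per column of `X` and keeps the
#' predictors whose permutation p value falls below `alpha`.
#'
#' @param Y Response matrix (transformed).
#' @param X Predictor matrix/data.frame.
#' @param alpha Retention level (default 0.05).
#' @param n_perm Permutations per marginal test.
#' @param seed Optional integer seed.
#' @return list with `retained` (character), `p_values` (named numeric);
#'   warns when nothing is retained.
#' @export
retain_significant <- function(Y, X, alpha = 0.05, n_perm = 999, seed = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- vapply(seq_len(ncol(X)), function(j) {
    csr_rda(Y, X[, j, drop = FALSE], n_perm = n_perm,
            seed = if (is.null(seed)) NULL else seed + j)$p_perm
  }, numeric(1))
  names(p) <- colnames(X)
  retained <- colnames(X)[p < alpha]
  if (length(retained) == 0) {
    warning("no predictor significant at alpha = ", alpha, call. = FALSE)
  }
  list(retained = retained, p_values = p, alpha = alpha)
}

#' Three-way variance partitioning of an RDA
#'
#' Computes the Ezekiel-adjusted R2 of the seven predictor subsets
#' \{1\}, \{2\}, \{3\}, \{1,2\}, \{1,3\}, \{2,3\}, \{1,2,3\} and decomposes
#' the full-model adj-R2 by inclusion-exclusion into unique fractions
#' (a, b, c), pairwise-shared fractions (d = 1&2, e = 1&3, f = 2&3) and the
#' three-way shared fraction g; individual fractions may be negative. The
#' "independent contribution" of a predictor — the quantity usually quoted
#' from a variance-partitioning Venn diagram — is the adj-R2 of its
#' singleton model.
#'
#' @param Y Response matrix (transformed).
#' @param X1,X2,X3 Single-predictor matrices/vectors.
#' @param labels Predictor names (defaults to x1, x2, x3).
#' @return Object of class `csr_varpart`: `subset_adj_r2` (7 values),
#'   `fractions` (a..g + residual), `independent` (3 singleton adj-R2).
#' @export
varpart3 <- function(Y, X1, X2, X3, labels = c("x1", "x2", "x3")) {
  Xs <- list(as.matrix(X1), as.matrix(X2), as.matrix(X3))
  for (i in 1:3) colnames(Xs[[i]]) <- labels[i]
  fit <- function(cols) {
    csr_rda(Y, do.call(cbind, Xs[cols]), n_perm = 0)$adj_r2
  }
  r <- c(`1` = fit(1), `2` = fit(2), `3` = fit(3),
         `12` = fit(c(1, 2)), `13` = fit(c(1, 3)), `23` = fit(c(2, 3)),
         `123` = fit(1:3))
  a <- r[["123"]] - r[["23"]]
  b <- r[["123"]] - r[["13"]]
  c_ <- r[["123"]] - r[["12"]]
  d <- r[["13"]] + r[["23"]] - r[["123"]] - r[["3"]]
  e <- r[["12"]] + r[["23"]] - r[["123"]] - r[["2"]]
  f <- r[["12"]] + r[["13"]] - r[["123"]] - r[["1"]]
  g <- r[["123"]] - a - b - c_ - d - e - f
  fractions <- c(a = a, b = b, c = c_, d = d, e = e, f = f, g = g,
                 residual = 1 - r[["123"]])
  structure(list(subset_adj_r2 = r,
                 fractions = fractions,
                 independent = stats::setNames(r[c("1", "2", "3")], labels),
                 labels = labels),
            class = "csr_varpart")
}

#' @export
print.csr_varpart <- function(x, ...) {
  cat("Variance partitioning (adjusted R2)\n")
  cat(sprintf("  full model [%s]: %.4f\n", paste(x$labels, collapse = "+"),
              x$subset_adj_r2[["123"]]))
  for (i in 1:3) {
    cat(sprintf("  independent %s: %.4f (unique %.4f)\n", x$labels[i],
                x$independent[[i]], x$fractions[[c("a", "b", "c")[i]]]))
  }
  invisible(x)
}
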