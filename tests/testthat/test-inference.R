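test_that("SRC equals the Pearson correlation for single-predictor fits", {
  # lm warns about the summary of an exact fit; the SRC itself is exact
  expect_equal(suppressWarnings(src_regression(c(2, 4, 6), c(1, 2, 3))$src), 1)
  set.seed(31)
  for (i in 1:25) {
    n <- sample(10:80, 1)
    x <- rnorm(n)
    y <- runif(1, -2, 2) * x + rnorm(n)
    res <- src_regression(y, x)
    expect_equal(res$src, cor(x, y), tolerance = 1e-12)
    expect_equal(res$p_value, cor.test(x, y)$p.value, tolerance = 1e-10)
    expect_true(abs(res$src) <= 1)
  }
  # large-n null: SRC near zero
  set.seed(32)
  x <- rnorm(5000); y <- rnorm(5000)
  expect_lt(abs(src_regression(y, x)$src), 0.05)
})

test_that("a constant response is flagged, not an error", {
  res <- src_regression(rep(0, 20), 1:20, group = "R-group",
                        predictor = "richness")
  expect_equal(res$note, "no variance")
  expect_true(is.na(res$src))
  expect_error(src_regression(1:5, rep(1, 5)), "constant")
})

test_that("the group model grid covers 4 groups x 3 predictors", {
  set.seed(33)
  cfg <- synthetic_config(seed = 77, plots_per_site = 8)
  land <- make_landscape(cfg)
  comm <- community_matrix(land$census)
  sites <- plot_sites(land$census)
  spectra <- plot_spectra(comm, csr_score(land$traits), sites)
  div <- diversity_indices(comm, sites)
  res <- group_diversity_models(spectra, div)
  expect_equal(nrow(res), 12L)
  expect_setequal(unique(res$predictor), c("richness", "abundance", "shannon"))
  adj <- group_diversity_models(spectra, div, adjust_site = TRUE)
  expect_equal(nrow(adj), 12L)
  expect_false(identical(res$src, adj$src))
})

test_that("group-proportion F matches explicit sums of squares and aov", {
  cen <- small_census()
  sp <- plot_spectra(community_matrix(cen), small_scores(), plot_sites(cen))
  got <- compare_group_proportions(sp, n_perm = 199, seed = 1)
  vals <- c(sp$p_c, sp$p_s, sp$p_r, sp$p_int)
  labs <- factor(rep(c("C", "S", "R", "Int"), each = nrow(sp)))
  f_aov <- summary(aov(vals ~ labs))[[1]]$`F value`[1]
  expect_equal(got$f_stat, f_aov, tolerance = 1e-10)
  expect_gte(got$p_perm, 1 / 200)

  # one group shifted far away drives p to the permutation floor
  sp2 <- data.frame(unit_id = sprintf("p%d", 1:20), level = "plot",
                    p_c = runif(20, 0.9, 1), p_s = runif(20, 0, 0.03))
  sp2$p_r <- runif(20, 0, 0.02)
  sp2$p_int <- 1 - sp2$p_c - sp2$p_s - sp2$p_r
  got2 <- compare_group_proportions(sp2, n_perm = 199, seed = 2)
  expect_equal(got2$p_perm, 1 / 200)
})

test_that("Hellinger rows have unit sum of squares and match closed forms", {
  expect_equal(hellinger(matrix(c(1, 1, 1, 1), 1))[1, ],
               rep(0.5, 4), ignore_attr = TRUE)
  expect_equal(hellinger(matrix(c(4, 1, 0, 0), 1))[1, ],
               c(sqrt(0.8), sqrt(0.2), 0, 0), ignore_attr = TRUE)
  set.seed(41)
  m <- matrix(rexp(60), 12, 5)
  expect_equal(rowSums(hellinger(m)^2), rep(1, 12), ignore_attr = TRUE)
  expect_error(hellinger(rbind(c(0, 0), c(1, 2))), "positive")
})

test_that("adjusted R2 follows the Ezekiel formula", {
  expect_equal(adjusted_r2(0.5, 11, 1), 1 - 0.5 * 10 / 9)
  expect_equal(adjusted_r2(0.37, 50, 0), 0.37)
  set.seed(42)
  for (i in 1:20) {
    r2 <- runif(1); n <- sample(10:200, 1); k <- sample(1:5, 1)
    expect_lte(adjusted_r2(r2, n, k), r2)
  }
})

test_that("RDA reproduces the brute-force oracle on the fixed fixture", {
  fx <- rda_fixture()
  fit <- csr_rda(fx$Y, fx$X, n_perm = 0)
  want <- oracle_rda(fx$Y, fx$X)
  expect_equal(unname(fit$eig_constrained), want$eig_constrained,
               tolerance = 1e-8)
  expect_equal(sort(fit$eig_residual, decreasing = TRUE),
               want$eig_residual, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$r2, want$r2, tolerance = 1e-10)
  expect_equal(fit$total_variance, want$total, tolerance = 1e-10)
  # scores agree up to per-axis sign
  for (j in seq_len(ncol(fit$site_scores))) {
    expect_equal(abs(fit$site_scores[, j]), abs(want$site_scores[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(abs(fit$response_scores[, j]),
                 abs(want$response_scores[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("RDA agrees with vegan on eigenvalues, R2 and adjusted R2", {
  fx <- rda_fixture()
  fit <- csr_rda(fx$Y, fx$X, n_perm = 0)
  vfit <- vegan::rda(fx$Y ~ richness + abundance + shannon,
                     data = as.data.frame(fx$X))
  expect_equal(unname(fit$eig_constrained), unname(vfit$CCA$eig),
               tolerance = 1e-8)
  expect_equal(fit$r2, vegan::RsquareAdj(vfit)$r.squared, tolerance = 1e-10)
  expect_equal(fit$adj_r2, vegan::RsquareAdj(vfit)$adj.r.squared,
               tolerance = 1e-10)
})

test_that("constrained plus residual variance equals total variance", {
  set.seed(51)
  for (i in 1:30) {
    n <- sample(12:40, 1)
    Y <- matrix(rnorm(n * 4), n, 4)
    X <- matrix(rnorm(n * 3), n, 3)
    fit <- csr_rda(Y, X, n_perm = 0)
    expect_equal(sum(fit$eig_constrained) + sum(fit$eig_residual),
                 fit$total_variance, tolerance = 1e-8)
  }
})

test_that("RDA degenerates to simple regression for a univariate response", {
  set.seed(52)
  x <- rnorm(30); y <- 0.7 * x + rnorm(30)
  fit <- csr_rda(matrix(y), matrix(x), n_perm = 0)
  expect_equal(fit$r2, cor(x, y)^2, tolerance = 1e-10)
})

test_that("perfect and null fits behave as expected under permutation", {
  set.seed(53)
  X <- matrix(rnorm(60), 20, 3)
  B <- matrix(runif(12, -1, 1), 3, 4)
  Y <- scale(X) %*% B
  fit <- csr_rda(Y, X, n_perm = 199, seed = 9)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_lt(sum(fit$eig_residual), 1e-10)
  expect_equal(fit$p_perm, 1 / 200)

  set.seed(54)
  n <- 120
  Ynull <- matrix(rnorm(n * 4), n, 4)
  Xnull <- matrix(rnorm(n * 3), n, 3)
  null_fit <- csr_rda(Ynull, Xnull, n_perm = 199, seed = 10)
  expect_lt(null_fit$r2, 3 * 3 / (n - 1) + 0.05)
  expect_gt(null_fit$p_perm, 0.05)
  expect_gte(null_fit$p_perm, 1 / 200)
})

test_that("collinear predictors are refused with a pointer to the VIF screen", {
  set.seed(55)
  x <- rnorm(25)
  X <- cbind(x, 2 * x, rnorm(25))
  Y <- matrix(rnorm(100), 25, 4)
  expect_error(csr_rda(Y, X), "collinear")
})

test_that("marginal retention keeps signal predictors and drops noise", {
  set.seed(56)
  n <- 100
  x1 <- rnorm(n)
  Y <- cbind(x1 + rnorm(n, sd = 0.4), -x1 + rnorm(n, sd = 0.4),
             rnorm(n), 0.5 * x1 + rnorm(n, sd = 0.4))
  X <- cbind(signal = x1, noise = rnorm(n))
  ret <- retain_significant(Y, X, alpha = 0.05, n_perm = 199, seed = 3)
  expect_equal(ret$retained, "signal")
  # alpha = 1 keeps everything
  ret_all <- retain_significant(Y, X, alpha = 1, n_perm = 99, seed = 3)
  expect_setequal(ret_all$retained, c("signal", "noise"))
  # nothing significant -> empty set with a warning
  Xn <- cbind(n1 = rnorm(n), n2 = rnorm(n))
  expect_warning(ret_none <- retain_significant(matrix(rnorm(n * 3), n),
                                                Xn, n_perm = 99, seed = 4),
                 "no predictor")
  expect_length(ret_none$retained, 0)
})

test_that("varpart fractions satisfy inclusion-exclusion exactly", {
  set.seed(57)
  for (i in 1:10) {
    n <- 60
    X1 <- rnorm(n); X2 <- 0.5 * X1 + rnorm(n); X3 <- rnorm(n)
    Y <- cbind(X1 + rnorm(n), X2 - X3 + rnorm(n), rnorm(n), X1 + X3 + rnorm(n))
    vp <- varpart3(Y, X1, X2, X3)
    expect_equal(sum(vp$fractions[c("a", "b", "c", "d", "e", "f", "g")]),
                 vp$subset_adj_r2[["123"]], tolerance = 1e-9)
    # singleton fractions equal the corresponding one-predictor adj-R2
    expect_equal(unname(vp$independent[1]),
                 csr_rda(Y, matrix(X1), n_perm = 0)$adj_r2, tolerance = 1e-12)
  }
})

test_that("a separable construction recovers its unique fraction", {
  set.seed(58)
  n <- 200
  X1 <- rnorm(n); X2 <- rnorm(n); X3 <- rnorm(n)
  Y <- cbind(X1 + rnorm(n, sd = 0.5), -X1 + rnorm(n, sd = 0.5),
             rnorm(n), rnorm(n))
  vp <- varpart3(Y, X1, X2, X3)
  expect_lt(abs(vp$fractions[["a"]] - vp$independent[[1]]), 0.02)
  expect_lt(max(abs(vp$fractions[c("b", "c", "d", "e", "f", "g")])), 0.02)
  expect_gt(vp$fractions[["a"]], 0.35)
})

test_that("varpart agrees with the vegan reference decomposition", {
  fx <- rda_fixture()
  set.seed(59)
  n <- nrow(fx$Y)
  vp <- varpart3(fx$Y, fx$X[, 1], fx$X[, 2], fx$X[, 3])
  vv <- vegan::varpart(fx$Y, fx$X[, 1, drop = FALSE],
                       fx$X[, 2, drop = FALSE], fx$X[, 3, drop = FALSE])
  # vegan lists fractions a..g in rows 1-7 and labels the pairwise ones
  # d = 1&2, e = 2&3, f = 1&3
  want <- vv$part$indfract$Adj.R.square[1:7]
  got <- unname(vp$fractions[c("a", "b", "c", "d", "f", "e", "g")])
  expect_equal(got, want, tolerance = 1e-6)
})
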