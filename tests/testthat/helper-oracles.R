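# Independent oracles and fixture builders shared across tests.

# Random trait triples spanning the calibration domain (log-uniform LA/SLA).
# The small corner where every axis value rescales to zero (tiny leaf, low
# SLA, low LDMC) has no defined strategy by construction, so it is resampled
# away to keep the triples scoreable.
random_traits <- function(n, seed = 1) {
  set.seed(seed)
  draw <- function(m) {
    data.frame(species_id = "", site_id = "sim",
               la = 10^stats::runif(m, 0, log10(894205)),
               sla = 10^stats::runif(m, log10(0.8), log10(80)),
               ldmc = stats::runif(m, 2, 85),
               stringsAsFactors = FALSE)
  }
  out <- draw(n)
  repeat {
    bad <- out$la < 30 & out$sla < 10 & out$ldmc < 17
    if (!any(bad)) break
    out[bad, ] <- draw(sum(bad))
  }
  out$species_id <- sprintf("sp%06d", seq_len(n))
  out
}

# Geometric oracle for the four-group partition: build the four midpoint
# sub-triangles in cartesian coordinates and classify a point by inclusive
# barycentric membership; points on a shared boundary belong to more than
# one sub-triangle and are assigned centrally (Int).
oracle_classify <- function(c_pct, s_pct, r_pct) {
  p <- c((s_pct + c_pct / 2) / 100, sqrt(3) / 2 * c_pct / 100)
  Rc <- c(0, 0); Sc <- c(1, 0); Cc <- c(0.5, sqrt(3) / 2)
  mRS <- (Rc + Sc) / 2; mSC <- (Sc + Cc) / 2; mRC <- (Rc + Cc) / 2
  tris <- list("C-group" = rbind(Cc, mSC, mRC),
               "S-group" = rbind(Sc, mRS, mSC),
               "R-group" = rbind(Rc, mRS, mRC),
               "Int-group" = rbind(mRS, mSC, mRC))
  eps <- 1e-9
  inside <- vapply(tris, function(tr) {
    lam <- solve(cbind(tr[2, ] - tr[1, ], tr[3, ] - tr[1, ]), p - tr[1, ])
    lam[1] >= -eps && lam[2] >= -eps && sum(lam) <= 1 + eps
  }, logical(1))
  hit <- names(tris)[inside]
  if (length(hit) == 1) hit else "Int-group"
}

# Brute-force RDA oracle: explicit projection matrix and eigenanalysis of
# the fitted/residual cross-product matrices (different code path from the
# package's QR/SVD route).
oracle_rda <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  Xs <- apply(X, 2, function(col) (col - mean(col)) / stats::sd(col))
  H <- Xs %*% solve(t(Xs) %*% Xs) %*% t(Xs)
  Yhat <- H %*% Yc
  Yres <- Yc - Yhat
  ec <- eigen(t(Yhat) %*% Yhat / (n - 1), symmetric = TRUE)
  er <- eigen(t(Yres) %*% Yres / (n - 1), symmetric = TRUE)
  keep <- ec$values > 1e-10
  list(eig_constrained = ec$values[keep],
       eig_residual = er$values[er$values > 1e-10],
       site_scores = Yhat %*% ec$vectors[, keep, drop = FALSE] / sqrt(n - 1),
       response_scores = ec$vectors[, keep, drop = FALSE],
       r2 = sum(Yhat^2) / sum(Yc^2),
       total = sum(Yc^2) / (n - 1))
}

# Fixed small RDA fixture (10 plots x 4 responses / 3 predictors).
rda_fixture <- function() {
  set.seed(202)
  X <- cbind(richness = stats::rpois(10, 20),
             abundance = stats::rpois(10, 90),
             shannon = stats::runif(10, 1, 3))
  comp <- matrix(stats::runif(40, 0.05, 1), 10, 4)
  comp <- comp + 0.4 * outer(scale(X[, 1])[, 1], c(1, -1, 0.2, 0.5))
  comp <- pmax(comp, 0.01)
  colnames(comp) <- c("p_c", "p_s", "p_r", "p_int")
  list(Y = csrspectra::hellinger(comp), X = X)
}

# Tiny two-site fixture used by core_data/spectrum tests.
small_census <- function() {
  data.frame(
    plot_id = c("p1", "p1", "p1", "p2", "p2", "p3"),
    site_id = c("a", "a", "a", "a", "a", "b"),
    species_id = c("sp1", "sp2", "sp3", "sp1", "sp3", "sp4"),
    stems = c(3L, 1L, 6L, 2L, 2L, 5L),
    stringsAsFactors = FALSE)
}

small_scores <- function() {
  data.frame(
    species_id = c("sp1", "sp2", "sp3", "sp4"),
    site_id = c("a", "a", "a", "b"),
    c_pct = c(60, 20, 10, 30), s_pct = c(20, 60, 30, 35),
    r_pct = c(20, 20, 60, 35), stringsAsFactors = FALSE)
}
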