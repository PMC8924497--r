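.default_archetypes <- function() {
  data.frame(
    archetype  = c("C", "S", "R", "Int"),
    la_meanlog = log(c(90000, 1200, 250, 2500)),
    la_sdlog   = c(0.50, 0.70, 0.55, 0.28),
    sla_meanlog = log(c(15, 5.5, 38, 19)),
    sla_sdlog  = c(0.22, 0.25, 0.22, 0.14),
    ldmc_shape1 = c(6, 30, 7, 24),
    ldmc_shape2 = c(18, 24, 40, 58),
    stringsAsFactors = FALSE
  )
}

.default_group_shares <- function() {
  list(
    tropical       = c(C = 0.24, S = 0.38, R = 0.00, Int = 0.38),
    subtropical    = c(C = 0.15, S = 0.27, R = 0.05, Int = 0.53),
    warm_temperate = c(C = 0.10, S = 0.34, R = 0.00, Int = 0.56),
    cold_temperate = c(C = 0.00, S = 1.00, R = 0.00, Int = 0.00)
  )
}

#' Configuration for the synthetic forest landscape generator
#'
#' The generator emulates the sampling design of a four-zone forest survey:
#' `n_sites` forest types with `plots_per_site` 0.04-ha plots each,
#' per-site species pools whose sizes default to the surveyed species
#' counts of [study_design()], per-plot richness drawn uniformly from a
#' site-specific range, Fisher log-series stem abundances, and per-species
#' leaf-trait triples drawn from log-normal (LA, SLA) and scaled-beta
#' (LDMC) distributions attached to four strategy archetypes. The share of
#' archetypes per site is chosen so that the scored pools loosely mimic the
#' qualitative ranking observed across climatic zones (an S-heavy
#' species-rich tropical pool, Int-heavy mid-latitude pools, ruderals only
#' in the subtropical pool, and a species-poor pure-S cold pool).
#'
#' `coupling_gamma` tilts the per-plot species draw toward C- and
#' Int-classified species by a factor exp(gamma * (richness - mean
#' richness)), creating the diversity-strategy association the inference
#' chain is meant to recover; `gamma = 0` removes the coupling.
#' `plot_noise_sd` adds a plot-level log-normal tilt to the same weights
#' regardless of richness, emulating compositional overdispersion among
#' plots.
#'
#' @param seed Integer seed (kept below 2^31 together with replicate
#'   offsets).
#' @param n_sites,plots_per_site Landscape dimensions.
#' @param site_names,pool_sizes,richness_range,group_shares,logseries_x
#'   Per-site settings; see defaults.
#' @param coupling_gamma Diversity-strategy coupling strength (per unit of
#'   richness).
#' @param plot_noise_sd SD of the plot-level compositional tilt (log
#'   scale).
#' @param archetypes Trait-distribution table (one row per archetype).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_sites = 4L,
                             plots_per_site = 50L,
                             site_names = study_design()$site_id,
                             pool_sizes = study_design()$n_species,
                             richness_range = list(c(20L, 60L), c(12L, 40L),
                                                   c(8L, 30L), c(2L, 7L)),
                             group_shares = .default_group_shares(),
                             logseries_x = rep(0.95, 4),
                             coupling_gamma = 0.06,
                             plot_noise_sd = 0.4,
                             archetypes = .default_archetypes()) {
  stopifnot(n_sites >= 1, plots_per_site >= 2,
            length(site_names) == n_sites, length(pool_sizes) == n_sites,
            length(richness_range) == n_sites,
            length(group_shares) == n_sites, length(logseries_x) == n_sites)
  for (i in seq_len(n_sites)) {
    rr <- richness_range[[i]]
    if (rr[1] < 1 || rr[2] < rr[1]) stop("invalid richness_range", call. = FALSE)
    if (rr[2] > pool_sizes[i]) {
      stop("richness_range exceeds pool size for site ", site_names[i],
           call. = FALSE)
    }
    s <- group_shares[[i]]
    if (any(s < 0) || abs(sum(s) - 1) > 1e-8) {
      stop("group_shares must be non-negative and sum to 1", call. = FALSE)
    }
    if (logseries_x[i] <= 0 || logseries_x[i] >= 1) {
      stop("logseries_x must lie in (0, 1)", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_sites = as.integer(n_sites),
                 plots_per_site = as.integer(plots_per_site),
                 site_names = site_names, pool_sizes = as.integer(pool_sizes),
                 richness_range = richness_range, group_shares = group_shares,
                 logseries_x = logseries_x,
                 coupling_gamma = coupling_gamma,
                 plot_noise_sd = plot_noise_sd,
                 archetypes = archetypes),
            class = "synthetic_config")
}

#' Exchangeable-plots null configuration
#'
#' A single homogeneous site: one species pool with all four strategy
#' groups represented, a common richness range and no diversity-strategy
#' coupling. Under this configuration the null hypothesis of the SRC slope
#' test is true by construction (plot composition is an exchangeable draw
#' from one pool, with expected group proportions independent of
#' richness), so it is the appropriate setting for checking the test's
#' type-I error rate. A site-structured landscape with `gamma = 0` is
#' not a null: between-site pool differences alone induce a real
#' diversity-composition association.
#'
#' @param seed Integer seed.
#' @param n_plots Number of plots.
#' @return A `synthetic_config`.
#' @export
null_config <- function(seed = 1L, n_plots = 200L) {
  synthetic_config(
    seed = seed, n_sites = 1L, plots_per_site = n_plots,
    site_names = "homogeneous", pool_sizes = 250L,
    richness_range = list(c(20L, 60L)),
    group_shares = list(homogeneous = c(C = 0.20, S = 0.30, R = 0.05,
                                        Int = 0.45)),
    logseries_x = 0.95, coupling_gamma = 0)
}

#' Sample from a (truncated) Fisher log-series distribution
#'
#' P(n) is proportional to x^n / n on n = 1, 2, ..., the classical
#' species-abundance distribution; sampling uses the inverse CDF on a
#' support truncated where the tail mass drops below 1e-9 (capped at
#' 100000).
#'
#' @param n Number of draws.
#' @param x Log-series parameter in (0, 1).
#' @return Integer vector of abundances (>= 1).
#' @export
rlogseries <- function(n, x) {
  if (x <= 0 || x >= 1) stop("x must lie in (0, 1)", call. = FALSE)
  kmax <- min(1e5, max(100, ceiling(log(1e-9) / log(x))))
  k <- seq_len(kmax)
  p <- x^k / k
  sample.int(kmax, n, replace = TRUE, prob = p)
}

#' Generate one site's species pool with traits and latent strategy
#'
#' Species are assigned to the four strategy archetypes by the site's
#' configured shares (largest-remainder rounding), traits drawn from the
#' archetype distributions (LDMC clamped to [0.5, 99.5]%, LA clamped to
#' the calibration maximum), and the pool scored with [csr_score()]; the
#' scored group is the species' latent strategy label used by the
#' diversity coupling.
#'
#' @param cfg A `synthetic_config`.
#' @param site Site index (1-based).
#' @param calibration CSR calibration (defaults to the packaged one).
#' @return list with `traits` (valid trait table) and `pool` (traits plus
#'   `archetype`, CSR percentages and `latent_group`). Draws from the
#'   current RNG state; seed externally (see [make_landscape()]).
#' @export
make_trait_pool <- function(cfg, site, calibration = stratefy_calibration()) {
  n <- cfg$pool_sizes[site]
  shares <- cfg$group_shares[[site]]
  base <- floor(shares * n)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(shares * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  arch <- rep(names(shares), times = base)
  at <- cfg$archetypes[match(arch, cfg$archetypes$archetype), ]
  la <- pmin(stats::rlnorm(n, at$la_meanlog, at$la_sdlog),
             calibration$axes$C$transform_constant)
  sla <- stats::rlnorm(n, at$sla_meanlog, at$sla_sdlog)
  ldmc <- pmin(pmax(100 * stats::rbeta(n, at$ldmc_shape1, at$ldmc_shape2),
                    0.5), 99.5)
  traits <- data.frame(
    species_id = sprintf("%s_sp%03d", cfg$site_names[site], seq_len(n)),
    site_id = cfg$site_names[site],
    la = la, sla = sla, ldmc = ldmc, stringsAsFactors = FALSE)
  traits <- validate_traits(traits)
  scores <- csr_score(traits, calibration)
  pool <- cbind(traits, archetype = arch,
                scores[c("c_pct", "s_pct", "r_pct")],
                latent_group = scores$group)
  list(traits = traits, pool = pool)
}

#' Generate a synthetic forest landscape
#'
#' Draws every site's species pool, then for each plot: a richness k
#' uniform in the site's range, a weighted sample (without replacement) of
#' k pool species — C/Int-classified species weighted by
#' exp(gamma * (k - mean richness) + plot tilt) — and log-series stem
#' counts per sampled species. The mean richness in the coupling is the
#' expected plot richness over the whole landscape, so the tilt is
#' positive in richer-than-average plots.
#'
#' @param cfg A `synthetic_config`.
#' @param calibration CSR calibration.
#' @return list with `census` (valid census table), `traits` (all sites'
#'   trait records) and `pools` (per-site pool tables with latent groups).
#' @export
make_landscape <- function(cfg, calibration = stratefy_calibration()) {
  set.seed(cfg$seed)
  mean_rich <- mean(vapply(cfg$richness_range, mean, numeric(1)))
  pools <- lapply(seq_len(cfg$n_sites), make_trait_pool, cfg = cfg,
                  calibration = calibration)
  census <- vector("list", cfg$n_sites)
  for (s in seq_len(cfg$n_sites)) {
    pool <- pools[[s]]$pool
    tilt_target <- pool$latent_group %in% c("C-group", "Int-group")
    rr <- cfg$richness_range[[s]]
    rows <- vector("list", cfg$plots_per_site)
    for (p in seq_len(cfg$plots_per_site)) {
      k <- if (rr[1] == rr[2]) rr[1] else sample(rr[1]:rr[2], 1)
      delta <- stats::rnorm(1, 0, cfg$plot_noise_sd)
      w <- ifelse(tilt_target,
                  exp(cfg$coupling_gamma * (k - mean_rich) + delta), 1)
      picked <- sample.int(nrow(pool), k, prob = w)
      rows[[p]] <- data.frame(
        plot_id = sprintf("%s_plot%02d", cfg$site_names[s], p),
        site_id = cfg$site_names[s],
        species_id = pool$species_id[picked],
        stems = rlogseries(k, cfg$logseries_x[s]),
        stringsAsFactors = FALSE)
    }
    census[[s]] <- do.call(rbind, rows)
  }
  census <- validate_census(do.call(rbind, census))
  traits <- do.call(rbind, lapply(pools, `[[`, "traits"))
  rownames(traits) <- NULL
  list(census = census, traits = traits,
       pools = stats::setNames(lapply(pools, `[[`, "pool"), cfg$site_names))
}

#' Run the scoring-to-SRC chain on replicated synthetic landscapes
#'
#' For each replicate, generates a landscape (seed = `cfg$seed` + 1000 *
#' replicate), scores the pools, builds plot spectra and diversity
#' indices, and fits the 12 group-by-predictor SRC models. The returned
#' table supports both power/sign-recovery summaries (coupled
#' configurations) and type-I calibration checks ([null_config()]).
#'
#' @param cfg A `synthetic_config`.
#' @param n_replicates Number of replicates.
#' @param adjust_site Passed to [group_diversity_models()].
#' @param calibration CSR calibration.
#' @return data.frame with columns `replicate`, `group`, `predictor`,
#'   `src`, `p_value`, `n`, `note`.
#' @export
recovery_experiment <- function(cfg, n_replicates = 100, adjust_site = FALSE,
                                calibration = stratefy_calibration()) {
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rcfg <- cfg
    rcfg$seed <- cfg$seed + 1000L * r
    land <- make_landscape(rcfg, calibration)
    scores <- csr_score(land$traits, calibration)
    comm <- community_matrix(land$census)
    sites <- plot_sites(land$census)
    spectra <- plot_spectra(comm, scores, sites)
    div <- diversity_indices(comm, sites)
    res <- group_diversity_models(spectra, div, adjust_site = adjust_site)
    res$replicate <- r
    out[[r]] <- res
  }
  do.call(rbind, out)
}
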