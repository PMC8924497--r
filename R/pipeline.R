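#' Default pipeline options
#'
#' @return Named list of the tunable options of [run_pipeline()] with
#'   their defaults.
#' @export
pipeline_defaults <- function() {
  list(dbh_filter = TRUE, shannon_base = exp(1), weighted_spectra = FALSE,
       alpha = 0.05, n_perm = 999L, seed = 17L)
}

.write_out <- function(df, dir, name, files) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  c(files, path)
}

#' Run the full strategy-spectrum analysis pipeline
#'
#' Orchestrates the stages in order: read/validate inputs, score species in
#' the CSR triangle, classify into the four strategy groups, build plot- and
#' forest-type-level spectra, compute diversity indices, VIF screen, SRC
#' models per group and predictor, group-proportion permutation test,
#' Hellinger transform, global RDA with permutation test, marginal
#' predictor retention at `alpha`, RDA on the retained set, and three-way
#' variance partitioning. All outputs are written as CSV plus a
#' machine-readable JSON manifest (package and calibration version, resolved
#' options, config hash, MD5 of every output); given the same inputs and
#' seed the manifest is byte-identical across runs.
#'
#' @param traits Trait table or path to a traits CSV. If `NULL`, a
#'   synthetic landscape is generated from `synthetic`.
#' @param census Census table or path to a census CSV (ignored when
#'   `traits` is `NULL`).
#' @param out_dir Output directory (created if needed).
#' @param calibration Path to a calibration CSV or a `csr_calibration`;
#'   defaults to the packaged table.
#' @param synthetic A `synthetic_config` used when no data are supplied.
#' @param config Optional path to a YAML file or named list overriding
#'   `options` fields (`dbh_filter`, `shannon_base`, `weighted_spectra`,
#'   `alpha`, `n_perm`, `seed`).
#' @param ... Individual option overrides, e.g. `n_perm = 199`.
#' @return (invisibly) list with all stage results and `manifest`.
#' @export
run_pipeline <- function(traits = NULL, census = NULL, out_dir,
                         calibration = NULL, synthetic = synthetic_config(),
                         config = NULL, ...) {
  opts <- pipeline_defaults()
  if (!is.null(config)) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    opts[names(config)] <- config
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(opts))
  if (length(bad)) stop("unknown option(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  opts[names(dots)] <- dots
  if (opts$alpha <= 0 || opts$alpha >= 1) stop("alpha must lie in (0, 1)",
                                               call. = FALSE)
  if (opts$n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)

  if (is.null(calibration)) {
    cal <- stratefy_calibration()
  } else if (is.character(calibration)) {
    cal <- read_calibration(calibration)
  } else cal <- calibration

  if (is.null(traits)) {
    synthetic$seed <- as.integer(opts$seed)
    land <- make_landscape(synthetic, cal)
    traits <- land$traits
    census <- land$census
    input_kind <- "synthetic"
  } else {
    if (is.character(traits)) traits <- read_traits(traits)
    if (is.character(census)) {
      census <- read_census(census, dbh_filter = opts$dbh_filter)
    }
    traits <- validate_traits(traits)
    census <- validate_census(census)
    input_kind <- "supplied"
  }

  missing_sp <- setdiff(
    .score_key(census$species_id, census$site_id),
    .score_key(traits$species_id, traits$site_id))
  if (length(missing_sp)) {
    stop("stage 'score': census species without trait records: ",
         paste(sort(unique(missing_sp)), collapse = "; "), call. = FALSE)
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  scores <- csr_score(traits, cal)
  scores <- cbind(scores, csr_coordinates(scores))
  files <- .write_out(scores, out_dir, "scores.csv", files)

  comm <- community_matrix(census)
  sites <- plot_sites(census)
  spectra <- plot_spectra(comm, scores, sites,
                          weighted = isTRUE(opts$weighted_spectra))
  files <- .write_out(spectra, out_dir, "spectra_plot.csv", files)
  spectra_site <- site_spectra(scores)
  files <- .write_out(spectra_site, out_dir, "spectra_site.csv", files)

  div <- diversity_indices(comm, sites, base = opts$shannon_base)
  files <- .write_out(div, out_dir, "diversity.csv", files)

  predictors <- as.matrix(div[c("richness", "abundance", "shannon")])
  vif_tab <- vif(predictors)
  files <- .write_out(vif_tab, out_dir, "vif.csv", files)

  src_tab <- group_diversity_models(spectra, div)
  files <- .write_out(src_tab, out_dir, "src_results.csv", files)

  comp <- compare_group_proportions(spectra, n_perm = opts$n_perm,
                                    seed = opts$seed)
  files <- .write_out(as.data.frame(comp), out_dir, "group_comparison.csv",
                      files)

  Y <- hellinger(as.matrix(spectra[c("p_c", "p_s", "p_r", "p_int")]))
  rownames(Y) <- spectra$unit_id
  rda_full <- csr_rda(Y, predictors, n_perm = opts$n_perm, seed = opts$seed)

  retention <- retain_significant(Y, predictors, alpha = opts$alpha,
                                  n_perm = opts$n_perm, seed = opts$seed)
  retained <- retention$retained
  rda_final <- if (length(retained) &&
                   length(retained) < ncol(predictors)) {
    csr_rda(Y, predictors[, retained, drop = FALSE],
            n_perm = opts$n_perm, seed = opts$seed)
  } else rda_full

  rda_summary <- data.frame(
    model = c("full", "retained"),
    predictors = c(paste(colnames(predictors), collapse = "+"),
                   paste(retained, collapse = "+")),
    r2 = c(rda_full$r2, rda_final$r2),
    adj_r2 = c(rda_full$adj_r2, rda_final$adj_r2),
    f_stat = c(rda_full$f_stat, rda_final$f_stat),
    p_perm = c(rda_full$p_perm, rda_final$p_perm),
    axis1_pct_total = c(rda_full$axis_pct_total[1],
                        rda_final$axis_pct_total[1]),
    axis2_pct_total = c(rda_full$axis_pct_total[2] %||% NA,
                        rda_final$axis_pct_total[2] %||% NA),
    stringsAsFactors = FALSE)
  files <- .write_out(rda_summary, out_dir, "rda_summary.csv", files)
  files <- .write_out(data.frame(unit_id = rownames(rda_final$site_scores),
                                 rda_final$site_scores),
                      out_dir, "rda_scores_sites.csv", files)
  files <- .write_out(data.frame(response = rownames(rda_final$response_scores),
                                 rda_final$response_scores),
                      out_dir, "rda_scores_responses.csv", files)
  files <- .write_out(data.frame(predictor = rownames(rda_final$predictor_scores),
                                 rda_final$predictor_scores),
                      out_dir, "rda_scores_predictors.csv", files)
  files <- .write_out(data.frame(p_marginal = retention$p_values,
                                 predictor = names(retention$p_values),
                                 retained = names(retention$p_values) %in%
                                   retained),
                      out_dir, "predictor_retention.csv", files)

  vp <- varpart3(Y, predictors[, "richness"], predictors[, "abundance"],
                 predictors[, "shannon"],
                 labels = c("richness", "abundance", "shannon"))
  vp_tab <- data.frame(fraction = names(vp$fractions),
                       adj_r2 = as.numeric(vp$fractions),
                       stringsAsFactors = FALSE)
  files <- .write_out(vp_tab, out_dir, "varpart_fractions.csv", files)

  cfg_json <- jsonlite::toJSON(opts[order(names(opts))], auto_unbox = TRUE,
                               digits = NA)
  cfg_file <- tempfile(); writeLines(as.character(cfg_json), cfg_file)
  manifest <- list(
    package = "csrspectra",
    version = as.character(utils::packageVersion("csrspectra")),
    calibration_version = cal$version,
    input_kind = input_kind,
    options = opts[order(names(opts))],
    config_md5 = unname(tools::md5sum(cfg_file)),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  unlink(cfg_file)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(scores = scores, spectra_plot = spectra,
                 spectra_site = spectra_site, diversity = div,
                 vif = vif_tab, src = src_tab, group_comparison = comp,
                 rda_full = rda_full, retention = retention,
                 rda_final = rda_final, varpart = vp,
                 manifest = manifest, manifest_path = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a
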