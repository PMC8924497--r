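#' Study design constants
#'
#' Sampling design of the four-forest survey the package emulates: four
#' climatic zones, 50 forest dynamics plots (0.04 ha, all stems with
#' DBH >= 1 cm) per zone, and the number of woody species sampled for leaf
#' traits in each zone. These counts are also the default species-pool
#' sizes of [synthetic_config()].
#'
#' @return A data.frame with one row per forest type: `site_id`, `climate`,
#'   `n_plots`, `n_species`.
#' @export
#' @examples
#' sum(study_design()$n_species)
study_design <- function() {
  data.frame(
    site_id   = c("tropical", "subtropical", "warm_temperate", "cold_temperate"),
    climate   = c("tropical", "subtropical", "warm-temperate", "cold-temperate"),
    n_plots   = c(50L, 50L, 50L, 50L),
    n_species = c(243L, 171L, 115L, 7L),
    stringsAsFactors = FALSE
  )
}

.trait_cols <- c("species_id", "site_id", "la", "sla", "ldmc")

.check_numeric_col <- function(raw, col) {
  v <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(v) & !is.na(raw) & trimws(as.character(raw)) != "")
  if (length(bad)) {
    stop(sprintf("column '%s' is not numeric at row(s) %s", col,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  v
}

#' Validate a species-by-site leaf-trait table
#'
#' Checks the invariants of a trait table: positive leaf area (`la`, mm^2)
#' and specific leaf area (`sla`, mm^2 mg^-1), leaf dry matter content
#' (`ldmc`, %) strictly inside (0, 100), and uniqueness of
#' (`species_id`, `site_id`) pairs. Violations raise errors indexed by row.
#'
#' @param traits data.frame with columns `species_id`, `site_id`, `la`,
#'   `sla`, `ldmc`.
#' @return The validated table, invisibly coerced to canonical column types.
#' @export
validate_traits <- function(traits) {
  missing <- setdiff(.trait_cols, names(traits))
  if (length(missing)) {
    stop("trait table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  traits$species_id <- as.character(traits$species_id)
  traits$site_id <- as.character(traits$site_id)
  for (col in c("la", "sla", "ldmc")) {
    traits[[col]] <- .check_numeric_col(traits[[col]], col)
    if (anyNA(traits[[col]])) {
      stop(sprintf("column '%s' has missing values at row(s) %s", col,
                   paste(which(is.na(traits[[col]])), collapse = ", ")),
           call. = FALSE)
    }
  }
  bad <- which(traits$la <= 0 | traits$sla <= 0 |
                 traits$ldmc <= 0 | traits$ldmc >= 100)
  if (length(bad)) {
    stop("invalid trait values (need la > 0, sla > 0, 0 < ldmc < 100) at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  key <- paste(traits$species_id, traits$site_id, sep = " @ ")
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    stop("duplicated (species_id, site_id) pair(s): ",
         paste(dup, collapse = "; "), call. = FALSE)
  }
  traits
}

#' Read a leaf-trait table from CSV
#'
#' Expects a UTF-8, comma-separated file with header columns `species_id`,
#' `site_id`, `la`, `sla`, `ldmc` ("." decimal separator). The table is
#' validated with [validate_traits()].
#'
#' @param path Path to the CSV file.
#' @return A validated trait data.frame.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_traits(df)
}

#' Derive species trait means from individual leaf measurements
#'
#' Computes per-leaf SLA = LA / LDW (mm^2 mg^-1) and LDMC = 100 * LDW / LFW
#' (%), then aggregates to one record per (species, site). The default
#' aggregation averages leaves within an individual first and then
#' individuals within a species, mirroring a sampling design of several
#' leaves from each of several individuals; `"pool_leaves"` averages all
#' leaves in one step.
#'
#' @param m data.frame with columns `species_id`, `site_id`, `lfw` (leaf
#'   fresh weight, mg), `ldw` (leaf dry weight, mg), `la` (leaf area, mm^2),
#'   and optionally `individual_id`. Without `individual_id` each row is
#'   treated as a single-leaf individual.
#' @param aggregate `"leaves_then_individuals"` (default) or `"pool_leaves"`.
#' @return data.frame with columns `species_id`, `site_id`, `la`, `sla`,
#'   `ldmc`, `n_individuals`. Not validated: boundary cases such as
#'   LDW = LFW (LDMC = 100%) are surfaced by [validate_traits()] downstream.
#' @export
traits_from_leaves <- function(m,
                               aggregate = c("leaves_then_individuals",
                                             "pool_leaves")) {
  aggregate <- match.arg(aggregate)
  need <- c("species_id", "site_id", "lfw", "ldw", "la")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    stop("leaf-measurement table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("lfw", "ldw", "la")) m[[col]] <- .check_numeric_col(m[[col]], col)
  bad <- which(m$la <= 0 | m$ldw <= 0 | m$lfw <= 0 | m$ldw > m$lfw)
  if (length(bad)) {
    stop("invalid leaf measurements (need la > 0 and 0 < ldw <= lfw) at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!"individual_id" %in% names(m)) m$individual_id <- seq_len(nrow(m))
  m$sla <- m$la / m$ldw
  m$ldmc <- 100 * m$ldw / m$lfw

  agg_mean <- function(df, by) {
    stats::aggregate(df[c("la", "sla", "ldmc")], by = df[by], FUN = mean)
  }
  if (aggregate == "leaves_then_individuals") {
    per_ind <- agg_mean(m, c("species_id", "site_id", "individual_id"))
    out <- agg_mean(per_ind, c("species_id", "site_id"))
    n_ind <- stats::aggregate(list(n_individuals = per_ind$individual_id),
                              by = per_ind[c("species_id", "site_id")],
                              FUN = length)
  } else {
    out <- agg_mean(m, c("species_id", "site_id"))
    n_ind <- stats::aggregate(
      list(n_individuals = m$individual_id),
      by = m[c("species_id", "site_id")],
      FUN = function(x) length(unique(x)))
  }
  out <- merge(out, n_ind, by = c("species_id", "site_id"), sort = TRUE)
  out[order(out$species_id, out$site_id), , drop = FALSE]
}

#' Validate a plot census table
#'
#' A census is a long-format table of stem counts per plot and species.
#' Each plot must belong to exactly one site (forest type) and counts must
#' be positive integers.
#'
#' @param census data.frame with columns `plot_id`, `site_id`, `species_id`,
#'   `stems`.
#' @return The validated census.
#' @export
validate_census <- function(census) {
  need <- c("plot_id", "site_id", "species_id", "stems")
  missing <- setdiff(need, names(census))
  if (length(missing)) {
    stop("census is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(census) == 0) stop("census table is empty", call. = FALSE)
  for (col in c("plot_id", "site_id", "species_id")) {
    census[[col]] <- as.character(census[[col]])
  }
  census$stems <- .check_numeric_col(census$stems, "stems")
  bad <- which(is.na(census$stems) | census$stems < 1 |
                 census$stems != round(census$stems))
  if (length(bad)) {
    stop("stems must be positive integers; offending row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  census$stems <- as.integer(round(census$stems))
  sites_per_plot <- tapply(census$site_id, census$plot_id,
                           function(x) length(unique(x)))
  multi <- names(sites_per_plot)[sites_per_plot > 1]
  if (length(multi)) {
    stop("plot(s) mapped to more than one site_id: ",
         paste(multi, collapse = ", "), call. = FALSE)
  }
  census
}

#' Read a plot census from CSV
#'
#' Accepts either an aggregated long table (`plot_id`, `site_id`,
#' `species_id`, `stems`) or per-stem records (`plot_id`, `site_id`,
#' `species_id`, `dbh_cm`, one row per stem). With per-stem records and
#' `dbh_filter = TRUE`, stems with DBH < 1 cm are dropped (the threshold is
#' inclusive: DBH = 1 cm is retained) before aggregation to counts.
#' Aggregated input is returned unchanged by the filter.
#'
#' @param path Path to the CSV file.
#' @param dbh_filter Apply the DBH >= 1 cm rule to per-stem records.
#' @return A validated census data.frame.
#' @export
read_census <- function(path, dbh_filter = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (nrow(df) == 0) stop("census file is empty: ", path, call. = FALSE)
  if (!"stems" %in% names(df) && "dbh_cm" %in% names(df)) {
    df$dbh_cm <- .check_numeric_col(df$dbh_cm, "dbh_cm")
    if (any(df$dbh_cm <= 0, na.rm = TRUE)) {
      stop("dbh_cm must be positive", call. = FALSE)
    }
    if (dbh_filter) df <- df[df$dbh_cm >= 1, , drop = FALSE]
    if (nrow(df) == 0) {
      stop("census file has no stems with DBH >= 1 cm", call. = FALSE)
    }
    df$stems <- 1L
    df <- stats::aggregate(list(stems = df$stems),
                           by = df[c("plot_id", "site_id", "species_id")],
                           FUN = sum)
  }
  validate_census(df)
}

#' Pivot a census into a plots x species count matrix
#'
#' @param census A validated census data.frame.
#' @return Integer matrix with plot ids as (sorted) row names and
#'   lexicographically sorted species ids as column names; absent
#'   plot-species combinations are 0. Row sums equal per-plot stem totals.
#' @export
community_matrix <- function(census) {
  census <- validate_census(census)
  tab <- stats::xtabs(stems ~ plot_id + species_id, data = census)
  m <- matrix(as.integer(tab), nrow = nrow(tab), ncol = ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

#' Melt a community matrix back to long format
#'
#' Inverse of [community_matrix()] up to row/column order; zero cells are
#' dropped. Site ids are not stored in the matrix and must be re-attached
#' from the census if needed.
#'
#' @param m plots x species count matrix with dimnames.
#' @return data.frame with columns `plot_id`, `species_id`, `stems`.
#' @export
matrix_to_long <- function(m) {
  idx <- which(m > 0, arr.ind = TRUE)
  out <- data.frame(plot_id = rownames(m)[idx[, 1]],
                    species_id = colnames(m)[idx[, 2]],
                    stems = as.integer(m[idx]),
                    stringsAsFactors = FALSE)
  out[order(out$plot_id, out$species_id), , drop = FALSE]
}

#' Map plots to their site (forest type)
#'
#' @param census A census data.frame.
#' @return Named character vector, `plot_id` -> `site_id`.
#' @export
plot_sites <- function(census) {
  census <- validate_census(census)
  u <- unique(census[c("plot_id", "site_id")])
  stats::setNames(u$site_id, u$plot_id)
}
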