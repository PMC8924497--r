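#' Ecological strategy spectrum of a labeled species set
#'
#' The spectrum of a community unit is the proportion of its species that
#' fall in each of the four strategy groups. Species are counted once
#' (presence-based) unless weights are supplied.
#'
#' @param groups factor/character vector of strategy-group labels, one per
#'   species (levels as in [classify_csr()]).
#' @param unit_id Identifier of the community unit (plot or site).
#' @param level `"plot"` or `"forest-type"`.
#' @param weights Optional non-negative weights (e.g. stem counts) for an
#'   abundance-weighted spectrum; `n_species` still counts species.
#' @return One-row data.frame: `unit_id`, `level`, `p_c`, `p_s`, `p_r`,
#'   `p_int`, `n_species`; the four proportions sum to 1.
#' @export
strategy_spectrum <- function(groups, unit_id = "unit", level = "plot",
                              weights = NULL) {
  if (length(groups) == 0) {
    stop("empty species set for unit '", unit_id, "'", call. = FALSE)
  }
  groups <- factor(groups, levels = .group_levels)
  if (anyNA(groups)) stop("unknown strategy-group label", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(groups))
  if (length(weights) != length(groups) || any(weights < 0) ||
      sum(weights) == 0) {
    stop("weights must be non-negative, same length as groups, not all zero",
         call. = FALSE)
  }
  w <- tapply(weights, groups, sum, default = 0)
  p <- as.numeric(w / sum(w))
  data.frame(unit_id = unit_id, level = level,
             p_c = p[1], p_s = p[2], p_r = p[3], p_int = p[4],
             n_species = length(groups), stringsAsFactors = FALSE)
}

.score_key <- function(species_id, site_id) paste(species_id, site_id, sep = " @ ")

#' Per-plot ecological strategy spectra
#'
#' For each plot, the species present (count > 0) are looked up in the
#' score table for that plot's site and their group labels summarized with
#' [strategy_spectrum()]. Stem counts do not enter the default
#' (presence-based) spectrum; `weighted = TRUE` weights species by stems
#' instead, as a sensitivity variant.
#'
#' @param comm plots x species count matrix.
#' @param scores Score table from [csr_score()] (must carry `group`;
#'   computed from the percentages if absent).
#' @param sites Named vector `plot_id -> site_id` (see [plot_sites()]).
#' @param weighted Weight species by stem counts instead of presence.
#' @return data.frame with one spectrum row per plot (`level = "plot"`).
#' @export
plot_spectra <- function(comm, scores, sites, weighted = FALSE) {
  comm <- as.matrix(comm)
  if (is.null(scores$group)) scores$group <- classify_csr(scores)
  if (anyNA(sites[rownames(comm)])) {
    stop("missing site_id for plot(s): ",
         paste(rownames(comm)[is.na(sites[rownames(comm)])], collapse = ", "),
         call. = FALSE)
  }
  lookup <- stats::setNames(as.character(scores$group),
                            .score_key(scores$species_id, scores$site_id))
  rows <- lapply(rownames(comm), function(p) {
    present <- comm[p, ] > 0
    if (!any(present)) stop("plot '", p, "' contains no species", call. = FALSE)
    keys <- .score_key(colnames(comm)[present], sites[[p]])
    g <- lookup[keys]
    if (anyNA(g)) {
      stop("no CSR score for species (at site ", sites[[p]], "): ",
           paste(colnames(comm)[present][is.na(g)], collapse = ", "),
           call. = FALSE)
    }
    strategy_spectrum(g, unit_id = p, level = "plot",
                      weights = if (weighted) comm[p, present] else NULL)
  })
  do.call(rbind, rows)
}

#' Forest-type (site-level) ecological strategy spectra
#'
#' Pools the species list of each site — every scored species counted once
#' — and summarizes the group labels. This is the species-pool spectrum,
#' not an average of plot spectra.
#'
#' @param scores Score table from [csr_score()].
#' @return data.frame with one spectrum row per site
#'   (`level = "forest-type"`).
#' @export
site_spectra <- function(scores) {
  if (is.null(scores$group)) scores$group <- classify_csr(scores)
  rows <- lapply(split(scores, scores$site_id), function(s) {
    strategy_spectrum(s$group, unit_id = s$site_id[1], level = "forest-type")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$unit_id), , drop = FALSE]
}
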