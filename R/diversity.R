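#' Per-plot diversity indices
#'
#' Computes, for each row (plot) of a community matrix, species richness
#' (number of species with positive count), stem abundance (total count)
#' and the Shannon-Wiener index H = -sum p_i log(p_i) over present species
#' (via [vegan::diversity()]). The natural logarithm is the default; other
#' bases can be requested. Plots with no stems get richness and abundance 0
#' and `NA` Shannon, with a warning.
#'
#' @param comm plots x species count matrix (see [community_matrix()]).
#' @param sites Optional named vector `plot_id -> site_id` (see
#'   [plot_sites()]); when supplied, a `site_id` column is attached.
#' @param base Logarithm base for the Shannon index (default `exp(1)`,
#'   i.e. nats).
#' @return data.frame with columns `plot_id`, (`site_id`,) `richness`,
#'   `abundance`, `shannon`.
#' @export
diversity_indices <- function(comm, sites = NULL, base = exp(1)) {
  comm <- as.matrix(comm)
  if (any(comm < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(comm))) {
    rownames(comm) <- sprintf("plot%d", seq_len(nrow(comm)))
  }
  richness <- as.integer(rowSums(comm > 0))
  abundance <- rowSums(comm)
  empty <- abundance == 0
  if (any(empty)) {
    warning(sum(empty), " plot(s) contain no stems; Shannon index set to NA",
            call. = FALSE)
  }
  shannon <- suppressWarnings(vegan::diversity(comm, index = "shannon",
                                               base = base))
  shannon[empty] <- NA_real_
  out <- data.frame(plot_id = rownames(comm),
                    richness = richness,
                    abundance = abundance,
                    shannon = as.numeric(shannon),
                    stringsAsFactors = FALSE)
  if (!is.null(sites)) {
    out$site_id <- unname(sites[out$plot_id])
    out <- out[c("plot_id", "site_id", "richness", "abundance", "shannon")]
  }
  out
}

#' Variance inflation factors of a predictor set
#'
#' VIF_j = 1 / (1 - R2_j), where R2_j is from an ordinary least-squares
#' regression (with intercept) of predictor j on the remaining predictors.
#' VIF > 10 is conventionally read as excessive collinearity; exactly
#' collinear predictors are reported as `Inf` and flagged rather than
#' raising an error.
#'
#' @param x Numeric matrix or data.frame of predictors (n rows, k >= 2
#'   non-constant columns, n > k).
#' @param threshold Flagging threshold (default 10).
#' @return data.frame with columns `predictor`, `vif`, `flagged`.
#' @export
vif <- function(x, threshold = 10) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least two predictors", call. = FALSE)
  if (nrow(x) <= ncol(x)) stop("need more rows than predictors", call. = FALSE)
  if (any(apply(x, 2, stats::sd) == 0)) {
    stop("predictors must be non-constant", call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  vals <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = colnames(x), vif = vals,
             flagged = !is.finite(vals) | vals > threshold,
             stringsAsFactors = FALSE)
}
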