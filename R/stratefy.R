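#' Read a CSR calibration table
#'
#' The calibration binds each CSR axis to one leaf trait (C <- LA,
#' S <- LDMC, R <- SLA), a trait transform, a fitted regression curve
#' mapping the transformed trait to a raw axis value, and the min/range
#' constants used to rescale raw values to 0-100 before the final
#' normalization. The package ships `stratefy_calibration_v1.csv`, a
#' transcription of the global leaf-trait calibration behind the StrateFy
#' tool of Pierce et al. (2017).
#'
#' @param path Path to a calibration CSV (see the packaged file for the
#'   schema).
#' @return An object of class `csr_calibration`: a list with `version` and
#'   one entry per axis.
#' @export
read_calibration <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("version", "axis", "source_trait", "transform",
            "transform_constant", "curve", "c0", "c1", "c2", "c3", "c4",
            "output_min", "output_range", "invert")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("calibration file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!identical(sort(df$axis), c("C", "R", "S"))) {
    stop("calibration must define exactly the three axes C, S, R",
         call. = FALSE)
  }
  expected_trait <- c(C = "LA", S = "LDMC", R = "SLA")
  axes <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    if (!identical(row$source_trait, unname(expected_trait[row$axis]))) {
      stop(sprintf("axis %s must be bound to trait %s (found %s)",
                   row$axis, expected_trait[row$axis], row$source_trait),
           call. = FALSE)
    }
    if (!is.finite(row$output_range) || row$output_range <= 0) {
      stop("output_range must be positive for axis ", row$axis, call. = FALSE)
    }
    list(axis = row$axis, source_trait = row$source_trait,
         transform = row$transform,
         transform_constant = row$transform_constant,
         curve = row$curve,
         coef = unlist(row[c("c0", "c1", "c2", "c3", "c4")], use.names = FALSE),
         output_min = row$output_min, output_range = row$output_range,
         invert = isTRUE(as.logical(row$invert)))
  })
  names(axes) <- df$axis
  structure(list(version = df$version[1],
                 axes = axes[c("C", "S", "R")]),
            class = "csr_calibration")
}

#' Load the packaged StrateFy-style calibration
#'
#' @return A `csr_calibration` object (see [read_calibration()]).
#' @export
stratefy_calibration <- function() {
  read_calibration(system.file("extdata", "stratefy_calibration_v1.csv",
                               package = "csrspectra", mustWork = TRUE))
}

#' Transform a raw trait value onto an axis' regression scale
#'
#' Three transforms are supported: `sqrt_global_prop`, 100 *
#' sqrt(value / global maximum), used for leaf area; `logit_fraction`,
#' logit of LDMC/100; and `natural_log`, used for SLA. Values outside the
#' transform's domain (non-positive traits, LDMC at or beyond 0/100) raise
#' a domain error.
#'
#' @param value Numeric vector of raw trait values.
#' @param axis One axis entry of a `csr_calibration` (e.g. `cal$axes$C`).
#' @return Numeric vector of transformed values.
#' @export
transform_trait <- function(value, axis) {
  if (any(!is.finite(value))) stop("trait values must be finite", call. = FALSE)
  switch(axis$transform,
    sqrt_global_prop = {
      if (any(value <= 0)) stop("leaf area must be positive", call. = FALSE)
      100 * sqrt(value / axis$transform_constant)
    },
    logit_fraction = {
      if (any(value <= 0 | value >= 100)) {
        stop("ldmc must lie strictly between 0 and 100%", call. = FALSE)
      }
      f <- value / 100
      log(f / (1 - f))
    },
    natural_log = {
      if (any(value <= 0)) stop("sla must be positive", call. = FALSE)
      log(value)
    },
    stop("unknown transform: ", axis$transform, call. = FALSE)
  )
}

.axis_curve <- function(z, axis) {
  k <- axis$coef
  switch(axis$curve,
    linear = k[1] + k[2] * z,
    double_exponential = k[1] + k[2] * (1 - exp(k[3] * z)) +
      k[4] * (1 - exp(k[5] * z)),
    exponential_decay = k[1] + k[2] * exp(k[3] * z),
    stop("unknown curve: ", axis$curve, call. = FALSE)
  )
}

.axis_value <- function(value, axis) {
  raw <- .axis_curve(transform_trait(value, axis), axis)
  v <- (raw - axis$output_min) / axis$output_range * 100
  if (axis$invert) v <- 100 - v
  pmin(pmax(v, 0), 100)
}

#' Score species in the CSR triangle from three leaf traits
#'
#' For each trait record, the calibrated pipeline is: transform the trait,
#' evaluate the axis regression curve, rescale by the calibration's
#' (min, range) to 0-100 (the R axis is inverted: SLA declines along the
#' raw axis), clamp to [0, 100], and normalize the three axis values so
#' that C + S + R = 100. Leaf areas above the calibration's global maximum
#' are clamped to it with a warning, since the curves are not validated
#' beyond the calibration data.
#'
#' @param traits Trait table as returned by [read_traits()] /
#'   [validate_traits()].
#' @param calibration A `csr_calibration`; defaults to the packaged one.
#' @return data.frame with columns `species_id`, `site_id`, `c_pct`,
#'   `s_pct`, `r_pct` (percentages summing to 100) and `group` (see
#'   [classify_csr()]).
#' @export
#' @examples
#' tr <- data.frame(species_id = "sp1", site_id = "a",
#'                  la = 2025, sla = 20, ldmc = 25)
#' csr_score(tr)
csr_score <- function(traits, calibration = stratefy_calibration()) {
  traits <- validate_traits(traits)
  la_max <- calibration$axes$C$transform_constant
  over <- traits$la > la_max
  if (any(over)) {
    warning(sprintf("%d leaf area value(s) above the calibration maximum (%g mm^2) were clamped",
                    sum(over), la_max), call. = FALSE)
    traits$la[over] <- la_max
  }
  vc <- .axis_value(traits$la, calibration$axes$C)
  vs <- .axis_value(traits$ldmc, calibration$axes$S)
  vr <- .axis_value(traits$sla, calibration$axes$R)
  tot <- vc + vs + vr
  degenerate <- tot <= 0
  if (any(degenerate)) {
    stop("degenerate CSR score (all axis values 0) for species: ",
         paste(paste(traits$species_id[degenerate],
                     traits$site_id[degenerate], sep = " @ "),
               collapse = "; "), call. = FALSE)
  }
  clamp01 <- function(x) pmin(pmax(x, 0), 100)  # guard rounding at 0/100
  out <- data.frame(species_id = traits$species_id,
                    site_id = traits$site_id,
                    c_pct = clamp01(100 * vc / tot),
                    s_pct = clamp01(100 * vs / tot),
                    r_pct = clamp01(100 * vr / tot),
                    stringsAsFactors = FALSE)
  out$group <- classify_csr(out)
  out
}

.group_levels <- c("C-group", "S-group", "R-group", "Int-group")

#' Classify CSR scores into the four midpoint strategy groups
#'
#' Connecting the midpoints of the three axes of the CSR triangle cuts it
#' into four sub-triangles: three corner regions, where one component
#' exceeds 50%, and the central region. The tie rule is strict: a component
#' at exactly 50% falls in the central (Int) group, so the corner regions
#' are open.
#'
#' @param scores data.frame with columns `c_pct`, `s_pct`, `r_pct` (summing
#'   to 100 within 1e-6 per row).
#' @return factor with levels `C-group`, `S-group`, `R-group`, `Int-group`.
#' @export
classify_csr <- function(scores) {
  cs <- cbind(scores$c_pct, scores$s_pct, scores$r_pct)
  if (any(abs(rowSums(cs) - 100) > 1e-6) || any(cs < -1e-9 | cs > 100 + 1e-9)) {
    stop("scores must be C/S/R percentages in [0, 100] summing to 100",
         call. = FALSE)
  }
  lab <- rep("Int-group", nrow(cs))
  lab[cs[, 1] > 50] <- "C-group"
  lab[cs[, 2] > 50] <- "S-group"
  lab[cs[, 3] > 50] <- "R-group"
  factor(lab, levels = .group_levels)
}

#' Cartesian plotting coordinates for CSR scores
#'
#' Ternary convention: R corner at (0, 0), S corner at (1, 0), C corner at
#' (1/2, sqrt(3)/2); x = (S + C/2)/100, y = (sqrt(3)/2) C / 100.
#'
#' @param scores data.frame with `c_pct`, `s_pct`, `r_pct`.
#' @return data.frame with columns `x`, `y`.
#' @export
csr_coordinates <- function(scores) {
  data.frame(x = (scores$s_pct + scores$c_pct / 2) / 100,
             y = sqrt(3) / 2 * scores$c_pct / 100)
}
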