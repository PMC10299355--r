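#' Classify green (vegetated) pixels in an RGB raster
#'
#' A pixel is called green when its excess-green index
#' `ExG = 2 G - R - B` exceeds `threshold`. ExG is a standard vegetation
#' index for 8-bit RGB imagery and replaces interactive color selection
#' with a deterministic, configurable rule.
#'
#' @param rgb numeric array `H x W x 3`, 8-bit scale (0-255).
#' @param threshold ExG threshold tau (default 20).
#' @param block_mask optional logical `H x W` matrix restricting the pixels
#'   considered (e.g. one block of a multi-block mosaic); pixels outside it
#'   are excluded from both counts.
#' @return list with `mask` (logical `H x W`; NA outside `block_mask`),
#'   `n_green`, and `n_total` (pixels considered).
#' @examples
#' px <- array(c(0, 255, 0), dim = c(1, 1, 3))
#' classify_green(px)$n_green
#' @export
classify_green <- function(rgb, threshold = 20, block_mask = NULL) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("`rgb` must be a 3-band (H x W x 3) array", call. = FALSE)
  exg <- 2 * rgb[, , 2] - rgb[, , 1] - rgb[, , 3]
  mask <- exg > threshold
  if (!is.null(block_mask)) {
    stopifnot(identical(dim(block_mask), dim(mask)))
    mask[!block_mask] <- NA
  }
  list(mask = mask, n_green = sum(mask, na.rm = TRUE),
       n_total = sum(!is.na(mask)))
}

#' Assign ground-survey damage categories
#'
#' Maps percent defoliation onto the five ordinal categories used by
#' ground-survey crews: none (0%), low (1-25%), medium (25-50%), high
#' (50-75%), severe (75-100%). The shared boundary values 25, 50 and 75
#' are assigned to the higher band so every percentage has exactly one
#' category.
#'
#' @param pct numeric vector of defoliation percentages in `[0, 100]`.
#' @return factor with levels `none < low < medium < high < severe`.
#' @examples
#' categorize_damage(c(0, 10, 50, 80))
#' @export
categorize_damage <- function(pct) {
  if (any(!is.finite(pct)) || any(pct < 0) || any(pct > 100))
    stop("defoliation percentages must lie in [0, 100]", call. = FALSE)
  lev <- c("none", "low", "medium", "high", "severe")
  out <- ifelse(pct == 0, "none",
         ifelse(pct < 25, "low",
         ifelse(pct < 50, "medium",
         ifelse(pct < 75, "high", "severe"))))
  factor(out, levels = lev, ordered = TRUE)
}

#' Estimate block defoliation from a green-pixel mask
#'
#' Defoliation is the percent reduction of the block's green-pixel fraction
#' relative to an undamaged reference area:
#' `defoliation_pct = 100 (1 - gf_block / gf_reference)`, clipped to
#' `[0, 100]`. Areas are scaled by the per-pixel ground footprint.
#'
#' @param green green-classification result from [classify_green()] (or any
#'   list with `n_green` and `n_total`).
#' @param reference_green_fraction green fraction of an undamaged reference
#'   area, > 0 (see [reference_green_fraction()]).
#' @param block_id block identifier.
#' @param pixel_area_m2 ground area of one pixel in square meters
#'   (default 0.02, i.e. roughly one soybean plant per pixel at a 50-m
#'   flight altitude).
#' @return one-row data frame (class `defoliation_report`) with columns
#'   `block_id`, `green_pixels`, `total_pixels`, `green_fraction`,
#'   `defoliation_pct`, `planted_area_ha`, `defoliated_area_ha`, `category`.
#' @export
estimate_block_defoliation <- function(green, reference_green_fraction,
                                       block_id = "block",
                                       pixel_area_m2 = 0.02) {
  stopifnot(is.list(green), !is.null(green$n_green), !is.null(green$n_total))
  if (!is.numeric(reference_green_fraction) || reference_green_fraction <= 0)
    stop("reference green fraction must be positive (uncalibratable otherwise)",
         call. = FALSE)
  if (green$n_total < 1) stop("block contains no pixels", call. = FALSE)
  gf <- green$n_green / green$n_total
  pct <- 100 * (1 - gf / reference_green_fraction)
  pct <- min(100, max(0, pct))
  planted_ha <- green$n_total * pixel_area_m2 / 1e4
  out <- data.frame(block_id = block_id,
                    green_pixels = green$n_green,
                    total_pixels = green$n_total,
                    green_fraction = gf,
                    defoliation_pct = pct,
                    planted_area_ha = planted_ha,
                    defoliated_area_ha = planted_ha * pct / 100,
                    category = categorize_damage(pct),
                    stringsAsFactors = FALSE)
  class(out) <- c("defoliation_report", class(out))
  out
}

#' Pick a reference green fraction
#'
#' When no undamaged reference polygon is designated, the block with the
#' highest green fraction is taken as the calibration reference.
#'
#' @param green_fractions numeric vector of per-block green fractions.
#' @return the maximum green fraction.
#' @export
reference_green_fraction <- function(green_fractions) {
  stopifnot(length(green_fractions) >= 1, all(is.finite(green_fractions)))
  gf <- max(green_fractions)
  if (gf <= 0)
    stop("no block has any green pixels; cannot calibrate", call. = FALSE)
  gf
}

#' Aggregate per-block defoliation reports to study totals
#'
#' The study-wide defoliation percentage is area-weighted:
#' `100 * sum(defoliated_area) / sum(planted_area)`.
#'
#' @param reports a data frame of rows produced by
#'   [estimate_block_defoliation()] (rbind-ed), or any data frame with
#'   `planted_area_ha`, `defoliated_area_ha` and `category` columns.
#' @return list with `n_blocks`, `planted_area_ha`, `defoliated_area_ha`,
#'   `overall_defoliation_pct`, `category_counts` and `category_shares_pct`
#'   (shares sum to 100).
#' @examples
#' r <- data.frame(planted_area_ha = c(10.11), defoliated_area_ha = c(7.92),
#'                 category = categorize_damage(78.3))
#' aggregate_reports(r)$overall_defoliation_pct
#' @export
aggregate_reports <- function(reports) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1)
  planted <- sum(reports$planted_area_ha)
  defol <- sum(reports$defoliated_area_ha)
  if (any(reports$defoliated_area_ha > reports$planted_area_ha + 1e-12))
    stop("defoliated area exceeds planted area in some block", call. = FALSE)
  cat_counts <- table(factor(reports$category,
                             levels = c("none", "low", "medium", "high", "severe")))
  list(n_blocks = nrow(reports),
       planted_area_ha = planted,
       defoliated_area_ha = defol,
       overall_defoliation_pct = 100 * defol / planted,
       category_counts = cat_counts,
       category_shares_pct = 100 * as.numeric(cat_counts) / nrow(reports))
}

#' Drop near-totally defoliated blocks before spatial analysis
#'
#' Blocks beyond the cutoff show near-complete defoliation and carry no
#' spatial pattern worth modelling; they are excluded from semivariogram
#' and SADIE analyses.
#'
#' @param reports defoliation report data frame.
#' @param max_defoliation exclusion cutoff in percent (default 95).
#' @return the filtered data frame.
#' @export
filter_spatial_blocks <- function(reports, max_defoliation = 95) {
  stopifnot(is.data.frame(reports))
  reports[reports$defoliation_pct <= max_defoliation, , drop = FALSE]
}
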