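#' Normalized difference vegetation index
#'
#' `NDVI = (NIR - Red) / (NIR + Red)` computed pixelwise from two
#' reflectance rasters. Pixels where `NIR + Red = 0` carry no signal and
#' are masked as `NA` (nodata). Inputs are assumed to be surface
#' reflectance already scaled to `[0, 1]`.
#'
#' @param nir,red numeric matrices of equal dimensions, values >= 0.
#' @param epoch optional epoch label (`"before"`, `"during"`, `"after"`)
#'   stored as an attribute.
#' @return matrix of NDVI values in `[-1, 1]` (class `ndvi_raster`), `NA`
#'   where undefined.
#' @examples
#' compute_ndvi(matrix(0.5), matrix(0.1))  # 0.6667
#' @export
compute_ndvi <- function(nir, red, epoch = NULL) {
  if (!identical(dim(nir), dim(red)))
    stop("NIR and Red rasters must share dimensions", call. = FALSE)
  if (any(nir < 0, na.rm = TRUE) || any(red < 0, na.rm = TRUE))
    stop("reflectances must be non-negative", call. = FALSE)
  s <- nir + red
  ndvi <- (nir - red) / s
  ndvi[!is.na(s) & s == 0] <- NA_real_
  attr(ndvi, "epoch") <- epoch
  class(ndvi) <- c("ndvi_raster", class(ndvi))
  ndvi
}

mask_summary <- function(delta, mask) {
  vals <- delta[mask & !is.na(mask)]
  list(n_pixels = sum(mask, na.rm = TRUE),
       min = if (length(vals)) min(vals) else NA_real_,
       max = if (length(vals)) max(vals) else NA_real_)
}

#' NDVI loss map (before minus during)
#'
#' Subtracts the during-outbreak NDVI from the pre-outbreak NDVI; pixels
#' whose loss exceeds `threshold` are flagged as damaged.
#'
#' @param before,during NDVI rasters (see [compute_ndvi()]) of equal
#'   dimensions.
#' @param threshold minimum NDVI drop counted as damage (default 0.05).
#' @return list with `loss` (matrix, `NA` where either input is nodata),
#'   `mask` (logical damage mask), and `summary` (pixel count, min/max
#'   loss over the mask).
#' @export
change_map <- function(before, during, threshold = 0.05) {
  if (!identical(dim(before), dim(during)))
    stop("NDVI rasters must share dimensions", call. = FALSE)
  loss <- unclass(before) - unclass(during)
  mask <- !is.na(loss) & loss > threshold
  list(loss = loss, mask = mask, threshold = threshold,
       summary = mask_summary(loss, mask))
}

#' NDVI gain map (after minus during)
#'
#' Subtracts the during-outbreak NDVI from the post-outbreak NDVI; pixels
#' whose gain exceeds `threshold` are flagged as regrown or replanted.
#'
#' @inheritParams change_map
#' @param after post-outbreak NDVI raster.
#' @return list with `gain`, `mask` (regrowth mask), and `summary`.
#' @export
regrowth_map <- function(after, during, threshold = 0.05) {
  if (!identical(dim(after), dim(during)))
    stop("NDVI rasters must share dimensions", call. = FALSE)
  gain <- unclass(after) - unclass(during)
  mask <- !is.na(gain) & gain > threshold
  list(gain = gain, mask = mask, threshold = threshold,
       summary = mask_summary(gain, mask))
}

#' Overlap of damage and regrowth masks
#'
#' Pixels flagged both as damaged (NDVI loss) and as regrown (NDVI gain):
#' areas hit by the outbreak that recovered or were replanted.
#'
#' @param damage_mask,regrowth_mask logical matrices of equal dimensions.
#' @return logical intersection mask.
#' @export
overlap_map <- function(damage_mask, regrowth_mask) {
  if (!identical(dim(damage_mask), dim(regrowth_mask)))
    stop("masks must share dimensions", call. = FALSE)
  damage_mask & regrowth_mask
}

#' Summarize an NDVI change analysis of a raster triplet
#'
#' Convenience wrapper: computes the three NDVI rasters from an
#' [generate_ndvi_triplet()]-shaped triplet (or any list with
#' `before`/`during`/`after` band pairs), the loss, gain and overlap maps,
#' and a JSON-ready summary.
#'
#' @param triplet list with epochs `before`, `during`, `after`, each
#'   holding `nir` and `red` matrices.
#' @param threshold change-detection threshold (default 0.05).
#' @return list with `ndvi` (three rasters), `damage`, `regrowth`,
#'   `overlap_mask`, and `summary`.
#' @export
ndvi_change_analysis <- function(triplet, threshold = 0.05) {
  stopifnot(all(c("before", "during", "after") %in% names(triplet)))
  nd <- lapply(c(before = "before", during = "during", after = "after"),
               function(e) compute_ndvi(triplet[[e]]$nir, triplet[[e]]$red, e))
  damage <- change_map(nd$before, nd$during, threshold)
  regrowth <- regrowth_map(nd$after, nd$during, threshold)
  overlap <- overlap_map(damage$mask, regrowth$mask)
  list(ndvi = nd, damage = damage, regrowth = regrowth,
       overlap_mask = overlap,
       summary = list(threshold = threshold,
                      loss = damage$summary, gain = regrowth$summary,
                      n_overlap = sum(overlap)))
}
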