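#' Variogram parameter set
#'
#' Bundles the three parameters of a bounded isotropic variogram model:
#' the nugget variance (micro-scale variation plus measurement error), the
#' partial sill (spatially structured variance), and the effective range
#' (the lag distance at which the semivariance reaches ~95% of its sill
#' for the asymptotic exponential/Gaussian models, and exactly its sill for
#' the spherical model).
#'
#' @param model one of `"exponential"`, `"spherical"`, `"gaussian"`.
#' @param nugget nugget variance C0, >= 0 (variance units).
#' @param partial_sill structural variance C, >= 0; `nugget + partial_sill`
#'   must be positive.
#' @param range_eff effective range in meters, > 0.
#' @return an object of class `variogram_params`.
#' @examples
#' variogram_params("spherical", nugget = 100, partial_sill = 900, range_eff = 200)
#' @export
variogram_params <- function(model = c("exponential", "spherical", "gaussian"),
                             nugget, partial_sill, range_eff) {
  model <- match.arg(model)
  stopifnot(is.numeric(nugget), nugget >= 0,
            is.numeric(partial_sill), partial_sill >= 0,
            is.numeric(range_eff), range_eff > 0)
  if (nugget + partial_sill <= 0)
    stop("nugget + partial_sill must be positive", call. = FALSE)
  structure(list(model = model, nugget = nugget,
                 partial_sill = partial_sill, range_eff = range_eff),
            class = "variogram_params")
}

#' Rectangular grid specification
#'
#' Defines the square-cell lattice used to aggregate defoliated-pixel
#' counts. The centroid of cell (row r, column c), 1-indexed, is
#' `origin + (c - 0.5, r - 0.5) * cell_size`.
#'
#' @param origin_xy numeric length-2, lattice origin in meters.
#' @param cell_size cell edge length in meters (default 54, the grid size
#'   used for block-level spatial analysis of defoliation counts).
#' @param n_rows,n_cols positive integers.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(origin_xy = c(0, 0), cell_size = 54, n_rows, n_cols) {
  stopifnot(length(origin_xy) == 2L, is.numeric(cell_size), cell_size > 0,
            n_rows >= 1, n_cols >= 1)
  structure(list(origin_xy = as.numeric(origin_xy),
                 cell_size = as.numeric(cell_size),
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "grid_spec")
}

#' Cell centroid coordinates of a grid
#'
#' @param grid a [grid_spec()].
#' @return data frame with columns `row`, `col`, `x`, `y` in row-major order.
#' @export
grid_centroids <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  rc <- expand.grid(col = seq_len(grid$n_cols), row = seq_len(grid$n_rows))
  data.frame(row = rc$row, col = rc$col,
             x = grid$origin_xy[1] + (rc$col - 0.5) * grid$cell_size,
             y = grid$origin_xy[2] + (rc$row - 0.5) * grid$cell_size)
}

# Correlogram of the three supported models under the effective-range
# convention (h and a in the same units).
variogram_correlation <- function(model, h, a) {
  switch(model,
    exponential = exp(-3 * h / a),
    spherical   = ifelse(h < a, 1 - 1.5 * (h / a) + 0.5 * (h / a)^3, 0),
    gaussian    = exp(-3 * (h / a)^2),
    stop("unknown variogram model: ", model, call. = FALSE))
}

# Theoretical semivariance gamma(h) for parameters (C0, C, a).
variogram_model_curve <- function(model, h, nugget, partial_sill, range_eff) {
  g <- nugget + partial_sill * (1 - variogram_correlation(model, h, range_eff))
  g[h == 0] <- 0
  g
}

#' Simulate a spatially structured damage field
#'
#' Draws a stationary Gaussian random field at the cell centroids of `grid`
#' with the covariance implied by `params` (Cholesky factorization of the
#' centroid covariance matrix), then maps it through the standard normal CDF
#' and an affine transform onto `[lo, hi]`. The CDF link keeps the marginal
#' damage level controllable independently of the variogram shape; at the
#' conventional unit total variance (`nugget + partial_sill = 1`) the
#' marginal is uniform on `[lo, hi]`, and in the vanishing-variance limit
#' the field collapses to the constant mid-level.
#'
#' @param params a [variogram_params()].
#' @param grid a [grid_spec()].
#' @param seed integer seed; identical seeds give bit-identical fields.
#' @param lo,hi bounds of the damage intensity scale (defaults 0 and 1,
#'   i.e. local defoliation from none to complete).
#' @return matrix `n_rows x n_cols` of damage intensities in `[lo, hi]`,
#'   with attributes `grid` and `params`.
#' @examples
#' p <- variogram_params("exponential", 0.2, 0.8, range_eff = 200)
#' f <- generate_damage_field(p, grid_spec(cell_size = 54, n_rows = 8, n_cols = 8), seed = 1)
#' @export
generate_damage_field <- function(params, grid, seed, lo = 0, hi = 1) {
  stopifnot(inherits(params, "variogram_params"), inherits(grid, "grid_spec"),
            lo >= 0, hi <= 1, lo < hi)
  cen <- grid_centroids(grid)
  n <- nrow(cen)
  total <- params$nugget + params$partial_sill
  if (params$partial_sill == 0) {
    z <- with_seed(seed, rnorm(n, sd = sqrt(params$nugget)))
  } else {
    h <- as.matrix(dist(cen[, c("x", "y")]))
    cov <- params$partial_sill * variogram_correlation(params$model, h, params$range_eff)
    diag(cov) <- total
    L <- tryCatch(chol(cov), error = function(e)
      stop(sprintf(paste0("covariance matrix not positive definite for ",
                          "model=%s, range_eff=%g, cell_size=%g: %s"),
                   params$model, params$range_eff, grid$cell_size,
                   conditionMessage(e)), call. = FALSE))
    z <- with_seed(seed, as.vector(crossprod(L, rnorm(n))))
  }
  # CDF link without standardization: at the conventional unit total
  # variance the marginal is uniform on [lo, hi]; as the total variance
  # shrinks the field collapses toward the constant mid-level, so the
  # zero-variance limit is a constant field.
  u <- pnorm(z)
  field <- matrix(lo + (hi - lo) * u, nrow = grid$n_rows, ncol = grid$n_cols,
                  byrow = TRUE)
  attr(field, "grid") <- grid
  attr(field, "params") <- params
  field
}

#' Render a damage field as an RGB scene with per-pixel truth
#'
#' Rasterizes each grid cell at `px_per_side^2` pixels. A pixel is rendered
#' as bare soil (defoliated) with probability equal to its cell's damage
#' intensity and as vegetation canopy otherwise; the realized choice is
#' recorded in the truth mask. Colors are drawn around vegetation
#' (60, 140, 60) and soil (150, 120, 90) centers with uniform integer
#' jitter of `+/- jitter` per channel, which keeps the two classes separable
#' by the excess-green index at the default threshold for all vegetation
#' pixels.
#'
#' @param field damage intensity matrix in `[0, 1]` (see
#'   [generate_damage_field()]).
#' @param grid the [grid_spec()] the field lives on.
#' @param px_per_side pixels per cell edge (default 20, i.e. 400 px/cell).
#' @param jitter per-channel color jitter amplitude in 8-bit counts
#'   (default 10; use 0 for exact-classification scenes).
#' @param seed integer seed.
#' @param veg,soil length-3 RGB class centers (8-bit).
#' @return an object of class `damage_scene`: list with `rgb`
#'   (H x W x 3 array, 0-255), `truth_mask` (H x W logical, TRUE =
#'   defoliated), `realized_fraction` and `cell_counts` (per-cell matrices),
#'   `grid`, `pixel_size_m` (= cell_size / px_per_side), and the raster
#'   origin. Image row 1 is the southernmost row (y increases with row).
#' @export
render_scene <- function(field, grid, px_per_side = 20, jitter = 10, seed = 1,
                         veg = c(60, 140, 60), soil = c(150, 120, 90)) {
  stopifnot(inherits(grid, "grid_spec"),
            nrow(field) == grid$n_rows, ncol(field) == grid$n_cols,
            all(field >= 0), all(field <= 1))
  if (px_per_side < 1) stop("px_per_side must be >= 1", call. = FALSE)
  px_per_side <- as.integer(px_per_side)
  H <- grid$n_rows * px_per_side
  W <- grid$n_cols * px_per_side
  # expand field to pixel resolution: pixel (i, j) belongs to cell
  # (ceil(i / pps), ceil(j / pps))
  rows <- ceiling(seq_len(H) / px_per_side)
  cols <- ceiling(seq_len(W) / px_per_side)
  p <- field[rows, cols, drop = FALSE]
  res <- with_seed(seed, {
    defol <- matrix(runif(H * W) < p, nrow = H)
    rgb <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) {
      base <- ifelse(defol, soil[ch], veg[ch])
      jit <- if (jitter > 0) sample(seq(-jitter, jitter), H * W, replace = TRUE) else 0
      rgb[, , ch] <- pmin(255, pmax(0, base + jit))
    }
    list(defol = defol, rgb = rgb)
  })
  cell_counts <- matrix(0L, grid$n_rows, grid$n_cols)
  for (r in seq_len(grid$n_rows)) {
    ri <- ((r - 1L) * px_per_side + 1L):(r * px_per_side)
    for (c in seq_len(grid$n_cols)) {
      ci <- ((c - 1L) * px_per_side + 1L):(c * px_per_side)
      cell_counts[r, c] <- sum(res$defol[ri, ci])
    }
  }
  structure(list(rgb = res$rgb, truth_mask = res$defol,
                 realized_fraction = cell_counts / px_per_side^2,
                 cell_counts = cell_counts, grid = grid,
                 px_per_side = px_per_side,
                 pixel_size_m = grid$cell_size / px_per_side,
                 origin_xy = grid$origin_xy),
            class = "damage_scene")
}

#' @export
print.damage_scene <- function(x, ...) {
  cat(sprintf("Synthetic damage scene: %d x %d px (%.3g m/px), %d x %d cells\n",
              nrow(x$truth_mask), ncol(x$truth_mask), x$pixel_size_m,
              x$grid$n_rows, x$grid$n_cols))
  cat(sprintf("  defoliated pixels: %d of %d (%.1f%%)\n", sum(x$truth_mask),
              length(x$truth_mask), 100 * mean(x$truth_mask)))
  invisible(x)
}

#' Generate before/during/after NIR and Red raster triplets
#'
#' Emulates satellite reflectance over an outbreak: before the outbreak the
#' whole scene carries the healthy NDVI target; during it, pixels flagged in
#' `truth_mask` drop to the damaged NDVI target; afterwards a seeded random
#' subset of the damaged pixels (fraction `regrowth_fraction`) reverts to
#' healthy, standing in for regrown or replanted crops. For an NDVI target
#' `v` the band pair is constructed with a fixed band sum `s`:
#' `red = s (1 - v) / 2`, `nir = s (1 + v) / 2`. Additive Gaussian noise is
#' clipped so reflectances stay in `[0, 1]`.
#'
#' @param truth_mask logical matrix, TRUE = damaged during the outbreak.
#' @param ndvi_healthy,ndvi_damaged NDVI targets, inside (-1, 1);
#'   defaults 0.8 (closed canopy) and 0.2 (bare/defoliated).
#' @param noise_sd reflectance noise standard deviation (default 0.01).
#' @param regrowth_fraction fraction of damaged pixels regrown by the after
#'   epoch (default 0.5).
#' @param band_sum NIR + Red total used to build the band pair (default 0.6).
#' @param seed integer seed.
#' @return class `ndvi_triplet`: list of epochs `before`, `during`, `after`
#'   (each a list with `nir` and `red` matrices), plus `damage_mask` and
#'   `regrowth_mask` truth matrices.
#' @export
generate_ndvi_triplet <- function(truth_mask, ndvi_healthy = 0.8,
                                  ndvi_damaged = 0.2, noise_sd = 0.01,
                                  regrowth_fraction = 0.5, band_sum = 0.6,
                                  seed = 1) {
  stopifnot(is.logical(truth_mask) || all(truth_mask %in% c(0, 1)))
  truth_mask <- matrix(as.logical(truth_mask), nrow = nrow(truth_mask))
  if (ndvi_healthy <= -1 || ndvi_healthy >= 1 ||
      ndvi_damaged <= -1 || ndvi_damaged >= 1)
    stop("NDVI targets must lie strictly inside (-1, 1)", call. = FALSE)
  stopifnot(noise_sd >= 0, regrowth_fraction >= 0, regrowth_fraction <= 1,
            band_sum > 0, band_sum <= 2)
  bands_for <- function(v) list(nir = band_sum * (1 + v) / 2,
                                red = band_sum * (1 - v) / 2)
  hb <- bands_for(ndvi_healthy)
  db <- bands_for(ndvi_damaged)
  dm <- dim(truth_mask)
  make_epoch <- function(damaged) {
    nir <- matrix(hb$nir, dm[1], dm[2]); nir[damaged] <- db$nir
    red <- matrix(hb$red, dm[1], dm[2]); red[damaged] <- db$red
    list(nir = nir, red = red)
  }
  with_seed(seed, {
    idx <- which(truth_mask)
    n_regrow <- round(regrowth_fraction * length(idx))
    regrow_idx <- if (n_regrow > 0) sample(idx, n_regrow) else integer(0)
    regrowth_mask <- matrix(FALSE, dm[1], dm[2])
    regrowth_mask[regrow_idx] <- TRUE
    after_damaged <- truth_mask & !regrowth_mask

    epochs <- list(before = make_epoch(matrix(FALSE, dm[1], dm[2])),
                   during = make_epoch(truth_mask),
                   after = make_epoch(after_damaged))
    if (noise_sd > 0) {
      epochs <- lapply(epochs, function(e) lapply(e, function(b)
        pmin(1, pmax(0, b + matrix(rnorm(length(b), sd = noise_sd), dm[1])))))
    }
    structure(c(epochs, list(damage_mask = truth_mask,
                             regrowth_mask = regrowth_mask)),
              class = "ndvi_triplet")
  })
}
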