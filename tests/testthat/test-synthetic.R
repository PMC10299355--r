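test_that("damage fields are reproducible and respect degenerate limits", {
  grid <- grid_spec(cell_size = 54, n_rows = 10, n_cols = 10)
  p <- variogram_params("exponential", nugget = 0.2, partial_sill = 0.8,
                        range_eff = 200)
  f1 <- generate_damage_field(p, grid, seed = 11)
  f2 <- generate_damage_field(p, grid, seed = 11)
  f3 <- generate_damage_field(p, grid, seed = 12)
  expect_identical(f1, f2)
  expect_false(identical(unclass(f1), unclass(f3)))
  expect_true(all(f1 >= 0 & f1 <= 1))

  # pure nugget: no structure beyond the nugget, flat semivariogram
  pn <- variogram_params("exponential", nugget = 1, partial_sill = 0,
                         range_eff = 100)
  fn <- generate_damage_field(pn, grid_spec(cell_size = 10, n_rows = 20,
                                            n_cols = 20), seed = 5)
  gc <- grid_counts(cbind(grid_centroids(attr(fn, "grid"))[, c("x", "y")],
                          count = as.vector(t(fn))))
  sv <- empirical_semivariogram(gc, n_bins = 8)
  slope <- stats::coef(stats::lm(gamma ~ lag, data = sv))[["lag"]]
  expect_lt(abs(slope * max(sv$lag)), 0.2 * mean(sv$gamma))

  # near-zero variance: field collapses to a constant
  p0 <- variogram_params("exponential", nugget = 0, partial_sill = 1e-12,
                         range_eff = 100)
  f0 <- generate_damage_field(p0, grid, seed = 1)
  expect_lt(max(f0) - min(f0), 1e-4)

  # nugget = partial_sill = 0 is rejected
  expect_error(variogram_params("exponential", 0, 0, 100), "positive")
})

test_that("rendered scenes record exact truth and binomial realization", {
  grid <- grid_spec(cell_size = 10, n_rows = 5, n_cols = 5)

  f0 <- matrix(0, 5, 5)
  s0 <- render_scene(f0, grid, px_per_side = 5, jitter = 0, seed = 1)
  expect_false(any(s0$truth_mask))
  expect_equal(classify_green(s0$rgb)$n_green, length(s0$truth_mask))

  f1 <- matrix(1, 5, 5)
  s1 <- render_scene(f1, grid, px_per_side = 5, jitter = 0, seed = 1)
  expect_true(all(s1$truth_mask))
  expect_equal(classify_green(s1$rgb)$n_green, 0)

  # conservation: per-cell truth counts sum to the scene-wide count
  p <- variogram_params("spherical", 0.1, 0.9, 120)
  fr <- generate_damage_field(p, grid, seed = 3)
  sc <- render_scene(fr, grid, px_per_side = 8, seed = 4)
  expect_identical(sum(sc$cell_counts), sum(sc$truth_mask))
  expect_identical(render_scene(fr, grid, px_per_side = 8, seed = 4)$rgb, sc$rgb)

  # field = 0.4 at 400 px/cell: every realized fraction inside the
  # binomial 99% family-level envelope (Bonferroni across the 25 cells)
  s4 <- render_scene(matrix(0.4, 5, 5), grid, px_per_side = 20, seed = 9)
  ci <- stats::qnorm(1 - 0.01 / (2 * 25)) * sqrt(0.4 * 0.6 / 400)
  expect_true(all(abs(s4$realized_fraction - 0.4) <= ci))
  expect_lt(abs(mean(s4$realized_fraction) - 0.4),
            2.576 * sqrt(0.4 * 0.6 / (400 * 25)))
})

test_that("NDVI triplets honor targets, regrowth fraction, and noise limits", {
  mask <- matrix(FALSE, 20, 20)
  mask[1:10, 1:6] <- TRUE  # 60 damaged pixels

  tr <- generate_ndvi_triplet(mask, noise_sd = 0, regrowth_fraction = 0, seed = 2)
  expect_identical(tr$after, tr$during)
  expect_false(any(tr$regrowth_mask))

  tr2 <- generate_ndvi_triplet(mask, ndvi_healthy = 0.8, ndvi_damaged = 0.2,
                               noise_sd = 0, regrowth_fraction = 0.5, seed = 2)
  nb <- compute_ndvi(tr2$before$nir, tr2$before$red)
  nd <- compute_ndvi(tr2$during$nir, tr2$during$red)
  diff <- unclass(nb) - unclass(nd)
  expect_equal(unique(diff[mask]), 0.6)
  expect_true(all(diff[!mask] == 0))
  expect_equal(sum(tr2$regrowth_mask), 30)
  expect_true(all(tr2$regrowth_mask[tr2$regrowth_mask] &
                    mask[tr2$regrowth_mask]))

  # all reflectances stay in [0, 1] even with noise
  tr3 <- generate_ndvi_triplet(mask, noise_sd = 0.3, seed = 7)
  for (e in c("before", "during", "after")) {
    expect_true(all(tr3[[e]]$nir >= 0 & tr3[[e]]$nir <= 1))
    expect_true(all(tr3[[e]]$red >= 0 & tr3[[e]]$red <= 1))
  }
  expect_identical(generate_ndvi_triplet(mask, noise_sd = 0.3, seed = 7), tr3)

  expect_error(generate_ndvi_triplet(mask, ndvi_healthy = 1.2), "inside")
})

test_that("rasters and block polygons round-trip through PNG/GeoJSON", {
  grid <- grid_spec(cell_size = 10, n_rows = 4, n_cols = 6)
  f <- generate_damage_field(variogram_params("gaussian", 0.3, 0.7, 30),
                             grid, seed = 8)
  sc <- render_scene(f, grid, px_per_side = 4, seed = 9)
  png_path <- tempfile(fileext = ".png")
  write_raster_png(sc$rgb, png_path, origin_xy = grid$origin_xy,
                   pixel_size = sc$pixel_size_m)
  back <- read_raster_png(png_path)
  expect_equal(back, sc$rgb, ignore_attr = TRUE)
  expect_equal(attr(back, "pixel_size"), sc$pixel_size_m)

  mask_path <- tempfile(fileext = ".png")
  write_raster_png(sc$truth_mask, mask_path)
  expect_equal(read_raster_png(mask_path) > 0.5, sc$truth_mask,
               ignore_attr = TRUE)

  blocks <- list(a = rbind(c(0, 0), c(60, 0), c(60, 40), c(0, 40)),
                 b = rbind(c(60, 0), c(100, 0), c(80, 40)))
  gj <- tempfile(fileext = ".geojson")
  write_blocks_geojson(blocks, gj)
  back_blocks <- read_blocks_geojson(gj)
  expect_named(back_blocks, c("a", "b"))
  expect_equal(back_blocks$a[1:4, ], blocks$a, ignore_attr = TRUE)
})
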