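test_that("grids cover block polygons with the minimal lattice", {
  sq108 <- rbind(c(0, 0), c(108, 0), c(108, 108), c(0, 108))
  g <- make_grid(sq108, 54)
  expect_equal(g$grid$n_rows * g$grid$n_cols, 4)
  expect_true(all(g$keep))

  sq100 <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  g2 <- make_grid(sq100, 54)
  expect_equal(sum(g2$keep), 4)  # partial edge cells kept

  # triangular block: corner cell without overlap dropped
  tri <- rbind(c(0, 0), c(108, 0), c(0, 108))
  g3 <- make_grid(tri, 54)
  expect_equal(sum(g3$keep), 3)

  expect_error(make_grid(sq108, 0), "positive")
  expect_error(make_grid(rbind(c(0, 0), c(1, 1), c(2, 2)), 54), "degenerate")
})

test_that("pixel counts are assigned by center containment and conserved", {
  # 4x4 pixel mask, pixel size 1, over a 2x2 grid of 2-m cells;
  # five defoliated pixels split 3 in the SW cell, 2 in the SE cell
  mask <- matrix(FALSE, 4, 4)
  mask[1, 1] <- mask[1, 2] <- mask[2, 1] <- TRUE  # SW cell (x<2, y<2)
  mask[1, 3] <- mask[2, 4] <- TRUE                # SE cell (x>2, y<2)
  grid <- grid_spec(origin_xy = c(0, 0), cell_size = 2, n_rows = 2, n_cols = 2)
  gc <- count_damage_per_cell(mask, grid, pixel_size = 1)
  expect_equal(sum(gc$count), 5)
  expect_equal(gc$count[gc$x == 1 & gc$y == 1], 3)
  expect_equal(gc$count[gc$x == 3 & gc$y == 1], 2)
  expect_equal(gc$count[gc$y == 3], c(0, 0))

  # uniform mask: equal counts everywhere; empty mask: zeros
  full <- matrix(TRUE, 8, 8)
  gfull <- count_damage_per_cell(full, grid_spec(cell_size = 4, n_rows = 2,
                                                 n_cols = 2), pixel_size = 1)
  expect_true(all(gfull$count == 16))
  gzero <- count_damage_per_cell(matrix(FALSE, 8, 8),
                                 grid_spec(cell_size = 4, n_rows = 2, n_cols = 2),
                                 pixel_size = 1)
  expect_true(all(gzero$count == 0))

  expect_error(count_damage_per_cell(matrix(TRUE, 20, 20),
                                     grid_spec(cell_size = 4, n_rows = 2,
                                               n_cols = 2), pixel_size = 1),
               "extent")
})

test_that("refining the grid preserves totals and quadruples cells", {
  set.seed(31)
  mask <- matrix(stats::runif(40 * 40) < 0.3, 40, 40)
  block <- rbind(c(0, 0), c(40, 0), c(40, 40), c(0, 40))
  g1 <- make_grid(block, 20)
  g2 <- make_grid(block, 10)
  c1 <- count_damage_per_cell(mask, g1$grid, pixel_size = 1)
  c2 <- count_damage_per_cell(mask, g2$grid, pixel_size = 1)
  expect_equal(nrow(c2), 4 * nrow(c1))
  expect_equal(sum(c1$count), sum(mask))
  expect_equal(sum(c2$count), sum(mask))
})

test_that("grid counts survive the x,y,count CSV exchange format", {
  gc <- grid_counts(data.frame(x = c(27, 81), y = c(27, 27), count = c(5L, 0L)),
                    cell_size = 54, block_id = "b7")
  path <- tempfile(fileext = ".csv")
  write_grid_counts(gc, path)
  expect_identical(readLines(path)[1], "x,y,count")
  back <- read_grid_counts(path)
  expect_equal(as.data.frame(back), as.data.frame(gc), ignore_attr = TRUE)
  expect_error(grid_counts(data.frame(x = 1, y = 1, count = -2)),
               "non-negative")
})
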