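test_that("excess-green classification follows the ExG threshold rule", {
  px <- array(0, dim = c(2, 2, 3))
  px[1, 1, ] <- c(0, 255, 0)     # ExG = 510 -> green
  px[1, 2, ] <- c(100, 100, 100) # ExG = 0 -> not green
  px[2, 1, ] <- c(60, 140, 60)   # vegetation center, ExG = 160 -> green
  px[2, 2, ] <- c(150, 120, 90)  # soil center, ExG = 0 -> not green
  g <- classify_green(px)
  expect_equal(g$n_green, 2)
  expect_true(g$mask[1, 1] && g$mask[2, 1])
  expect_false(g$mask[1, 2] || g$mask[2, 2])

  bm <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)  # first column only
  gb <- classify_green(px, block_mask = bm)
  expect_equal(gb$n_total, 2)
  expect_equal(gb$n_green, 2)

  expect_error(classify_green(matrix(1, 2, 2)), "3-band")
})

test_that("calibrated defoliation follows percent reduction in green fraction", {
  mk <- function(n_green, n_total) list(n_green = n_green, n_total = n_total)
  r_eq <- estimate_block_defoliation(mk(80, 100), reference_green_fraction = 0.8)
  expect_equal(r_eq$defoliation_pct, 0)
  r_zero <- estimate_block_defoliation(mk(0, 100), reference_green_fraction = 0.8)
  expect_equal(r_zero$defoliation_pct, 100)
  expect_equal(r_zero$defoliated_area_ha, r_zero$planted_area_ha)

  # clipping when a block is greener than the reference
  r_over <- estimate_block_defoliation(mk(95, 100), reference_green_fraction = 0.9)
  expect_equal(r_over$defoliation_pct, 0)

  # monotone: defoliation strictly decreases as green fraction rises
  pcts <- vapply(seq(5, 75, by = 10), function(gp)
    estimate_block_defoliation(mk(gp, 100), 0.8)$defoliation_pct, 0)
  expect_true(all(diff(pcts) < 0))

  expect_error(estimate_block_defoliation(mk(1, 10), 0), "positive")
})

test_that("damage categories use half-open bands closed at the upper band", {
  expect_equal(as.character(categorize_damage(c(0, 10, 25, 40, 50, 60, 75, 80, 100))),
               c("none", "low", "medium", "medium", "high", "high",
                 "severe", "severe", "severe"))
  expect_true(is.ordered(categorize_damage(50)))
  expect_error(categorize_damage(101), "\\[0, 100\\]")
  expect_error(categorize_damage(-1), "\\[0, 100\\]")
})

test_that("study aggregation is area-weighted and shares sum to 100", {
  one <- data.frame(planted_area_ha = 2, defoliated_area_ha = 1,
                    category = categorize_damage(50))
  expect_equal(aggregate_reports(one)$overall_defoliation_pct, 50)

  two <- data.frame(planted_area_ha = c(1, 1), defoliated_area_ha = c(0.2, 0.8),
                    category = categorize_damage(c(20, 80)))
  agg <- aggregate_reports(two)
  expect_equal(agg$overall_defoliation_pct, 50)
  expect_equal(sum(agg$category_shares_pct), 100)
})

test_that("defoliation recovers rendered truth on zero-jitter scenes", {
  grid <- grid_spec(cell_size = 10, n_rows = 6, n_cols = 6)
  p <- variogram_params("exponential", 0.3, 0.7, 80)
  f <- generate_damage_field(p, grid, seed = 21)
  sc <- render_scene(f, grid, px_per_side = 10, jitter = 0, seed = 22)
  g <- classify_green(sc$rgb)
  # zero jitter: classification equals truth exactly
  expect_identical(g$mask, !sc$truth_mask)
  rep <- estimate_block_defoliation(g, reference_green_fraction = 1,
                                    block_id = "b1")
  truth_pct <- 100 * mean(sc$truth_mask)
  expect_lt(abs(rep$defoliation_pct - truth_pct), 0.5)
  expect_equal(as.character(rep$category),
               as.character(categorize_damage(truth_pct)))
})

test_that("near-complete defoliation blocks are excluded from spatial analysis", {
  reps <- data.frame(block_id = c("a", "b", "c"),
                     defoliation_pct = c(40, 95, 99))
  kept <- filter_spatial_blocks(reps)
  expect_equal(kept$block_id, c("a", "b"))
})
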