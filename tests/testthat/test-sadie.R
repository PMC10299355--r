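test_that("distance to regularity solves the transportation problem exactly", {
  # uniform counts: nothing to move
  u <- grid_counts(data.frame(x = 1:4, y = rep(1, 4), count = 3L))
  r0 <- distance_to_regularity(u)
  expect_equal(r0$D, 0)
  expect_equal(nrow(r0$flows), 0)

  # two cells 10 m apart, counts (2, 0): one unit moves 10 m
  two <- grid_counts(data.frame(x = c(0, 10), y = c(0, 0), count = c(2L, 0L)))
  r2 <- distance_to_regularity(two)
  expect_equal(r2$D, 10)
  expect_equal(r2$flows$flow, 1)

  expect_error(distance_to_regularity(
    data.frame(x = 1:2, y = 1:2, count = c(-1, 3))), "non-negative")

  # random 4x4 instances against the independent LP oracle
  set.seed(51)
  insts <- list(); ours <- numeric(0)
  for (k in 1:12) {
    gc <- random_grid_counts(4, 4, lambda = 4)
    ours[k] <- distance_to_regularity(gc)$D
    insts[[k]] <- list(x = gc$x, y = gc$y, counts = gc$count)
  }
  oracle <- lp_transport_oracle(insts)
  expect_equal(ours, oracle, tolerance = 1e-9)
})

test_that("SADIE inference is seeded, deterministic, and detects patches", {
  qc <- quadrant_counts()
  s1 <- sadie(qc, K = 199, seed = 5)
  s2 <- sadie(qc, K = 199, seed = 5)
  expect_identical(s1[c("D", "Ia", "Pa", "v", "vbar_i", "vbar_j")],
                   s2[c("D", "Ia", "Pa", "v", "vbar_i", "vbar_j")])

  expect_gt(s1$Ia, 1)
  expect_lt(s1$Pa, 0.05)
  expect_gt(s1$vbar_i, 1.5)
  expect_lt(s1$vbar_j, -1.5)
  # patch units are the high-count quadrant
  expect_true(all(s1$side[qc$count > mean(qc$count)] == "patch"))
  expect_equal(sum(s1$side == "gap"), sum(qc$count < mean(qc$count)))

  # uniform counts: indices undefined, reported as NA
  su <- sadie(grid_counts(data.frame(x = 1:5, y = rep(2, 5), count = 4L)),
              K = 19, seed = 1)
  expect_equal(su$D, 0)
  expect_true(is.na(su$Ia) && is.na(su$Pa))

  expect_error(sadie(qc, K = 10), "at least 19")
})

test_that("Ia is invariant to count shifts and coordinate isometries", {
  set.seed(53)
  gc <- random_grid_counts(5, 5, lambda = 5)
  s <- sadie(gc, K = 99, seed = 7)

  shifted <- gc
  shifted$count <- shifted$count + 11L
  ss <- sadie(shifted, K = 99, seed = 7)
  expect_equal(ss$D, s$D)
  expect_equal(ss$Ia, s$Ia)
  expect_equal(ss$Pa, s$Pa)

  th <- pi / 6
  rot <- gc
  rot$x <- cos(th) * gc$x - sin(th) * gc$y + 100
  rot$y <- sin(th) * gc$x + cos(th) * gc$y - 40
  sr <- sadie(grid_counts(rot), K = 99, seed = 7)
  expect_equal(sr$D, s$D, tolerance = 1e-10)
  expect_equal(sr$Ia, s$Ia, tolerance = 1e-10)

  sc <- gc
  sc$x <- gc$x * 2.5
  sc$y <- gc$y * 2.5
  s2 <- sadie(grid_counts(sc), K = 99, seed = 7)
  expect_equal(s2$D, 2.5 * s$D, tolerance = 1e-10)
  expect_equal(s2$Ia, s$Ia, tolerance = 1e-10)
  expect_equal(s2$Pa, s$Pa)
})

test_that("summary, print, plot and CSV export expose the result table", {
  s <- sadie(quadrant_counts(), K = 49, seed = 9)
  sm <- summary(s)
  expect_named(sm, c("n_units", "K", "D", "Ia", "Pa", "vbar_j", "vbar_i",
                     "Pvj", "Pvi"))
  expect_output(print(s), "index of aggregation")
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_sadie(s, p1, p2)
  expect_equal(nrow(read.csv(p2)), 64)
  expect_named(read.csv(p2), c("unit", "x", "y", "count", "side", "v"))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(s))
})
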