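# Independent oracles and fixture builders shared across test files.

# All-pairs brute-force Matheron estimator: plain double loop, no shared
# code with empirical_semivariogram().
brute_semivariogram <- function(counts, n_bins, max_lag) {
  n <- nrow(counts)
  gsum <- numeric(n_bins)
  np <- integer(n_bins)
  bw <- max_lag / n_bins
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      h <- sqrt((counts$x[i] - counts$x[j])^2 + (counts$y[i] - counts$y[j])^2)
      if (h > 0 && h <= max_lag) {
        b <- min(n_bins, ceiling(h / bw))
        gsum[b] <- gsum[b] + (counts$count[i] - counts$count[j])^2
        np[b] <- np[b] + 1L
      }
    }
  }
  keep <- np > 0
  data.frame(lag = ((seq_len(n_bins)) - 0.5) * bw,
             gamma = ifelse(np > 0, gsum / (2 * np), NA),
             n_pairs = np)[keep, , drop = FALSE]
}

# scipy.optimize.linprog (HiGHS) through the system python: a generic LP
# solve of the same transportation problems, fully independent of the
# package's transportation simplex.
lp_transport_oracle <- function(instances) {
  script <- system.file("oracle", "transport_lp.py", package = "defolmap")
  inp <- tempfile(fileext = ".json")
  jsonlite::write_json(instances, inp, auto_unbox = FALSE, digits = NA)
  out <- system2("python", c(script, inp), stdout = TRUE, stderr = "")
  jsonlite::fromJSON(paste(out, collapse = ""))
}

# Random grid-count instance on an r x c lattice.
random_grid_counts <- function(n_rows, n_cols, lambda = 5, spacing = 10) {
  g <- expand.grid(x = seq_len(n_cols) * spacing - spacing / 2,
                   y = seq_len(n_rows) * spacing - spacing / 2)
  g$count <- stats::rpois(nrow(g), lambda)
  grid_counts(g)
}

# 8 x 8 lattice with a single high-count quadrant (strongly patched).
quadrant_counts <- function(high = 12L, low = 1L) {
  g <- expand.grid(x = seq(5, 75, by = 10), y = seq(5, 75, by = 10))
  g$count <- ifelse(g$x < 40 & g$y < 40, high, low)
  grid_counts(g)
}
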