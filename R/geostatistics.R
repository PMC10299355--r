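#' Empirical semivariogram (Matheron estimator)
#'
#' Bins all point pairs by separation distance and computes the classical
#' Matheron estimator per bin,
#' `gamma(h) = sum over pairs (z_i - z_j)^2 / (2 N(h))`.
#'
#' @param counts a `grid_counts` data frame (columns `x`, `y`, `count`), or
#'   any data frame with those columns.
#' @param n_bins number of equal-width lag bins between 0 and `max_lag`
#'   (default 12).
#' @param max_lag active lag distance in meters; defaults to half the
#'   maximum inter-point distance.
#' @return class `semivariogram`: data frame with columns `lag` (bin
#'   midpoint), `gamma`, `n_pairs`; empty bins are dropped. Attributes
#'   `bin_width` and `max_lag`.
#' @examples
#' gc <- grid_counts(data.frame(x = c(0, 10), y = c(0, 0), count = c(0, 2)))
#' empirical_semivariogram(gc, n_bins = 1, max_lag = 15)
#' @export
empirical_semivariogram <- function(counts, n_bins = 12, max_lag = NULL) {
  stopifnot(is.data.frame(counts), all(c("x", "y", "count") %in% names(counts)),
            n_bins >= 1)
  n <- nrow(counts)
  if (n < 2) stop("need at least 2 points", call. = FALSE)
  d <- as.vector(dist(counts[, c("x", "y")]))
  if (max(d) <= 0) stop("all points are coincident", call. = FALSE)
  if (is.null(max_lag)) max_lag <- max(d) / 2
  stopifnot(max_lag > 0)
  dz2 <- as.vector(dist(counts$count))^2
  use <- d <= max_lag & d > 0
  if (!any(use)) stop("no point pairs within max_lag", call. = FALSE)
  bw <- max_lag / n_bins
  bin <- pmin(n_bins, ceiling(d[use] / bw))
  np <- tabulate(bin, nbins = n_bins)
  gsum <- vapply(seq_len(n_bins), function(b) sum(dz2[use][bin == b]), 0)
  keep <- np > 0
  out <- data.frame(lag = (seq_len(n_bins) - 0.5) * bw,
                    gamma = ifelse(np > 0, gsum / (2 * np), NA_real_),
                    n_pairs = np)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bin_width") <- bw
  attr(out, "max_lag") <- max_lag
  class(out) <- c("semivariogram", "data.frame")
  out
}

#' Fit a theoretical variogram model to an empirical semivariogram
#'
#' Least-squares fit of one of three bounded models, parameterized by the
#' effective range `a` (lag at ~95% of the sill for the asymptotic models):
#' \describe{
#'   \item{exponential}{`C0 + C (1 - exp(-3 h / a))`}
#'   \item{spherical}{`C0 + C (1.5 h/a - 0.5 (h/a)^3)` for `h <= a`, else `C0 + C`}
#'   \item{gaussian}{`C0 + C (1 - exp(-3 (h/a)^2))`}
#' }
#' subject to `C0 >= 0`, `C >= 0`, `a > 0`. Minimization profiles out the
#' linear parameters: for a fixed range the non-negative (C0, C) pair has a
#' closed-form least-squares solution, and the range is located by a dense
#' log-spaced grid search with golden-section refinement — deterministic
#' and robust to the spherical model's derivative kink. By default plain
#' (unweighted) RSS, matching model selection by minimum RSS and maximum
#' r-squared. The fit also reports the degree of spatial dependence
#' `DD = 100 (sill_total - C0) / sill_total` (see [spatial_dependence()]).
#'
#' @param sv a [empirical_semivariogram()] result (or data frame with
#'   `lag`, `gamma`, and optionally `n_pairs`).
#' @param model `"exponential"`, `"spherical"`, or `"gaussian"`.
#' @param weights `"none"` (default) for plain RSS, `"npairs"` to weight
#'   squared residuals by pair counts.
#' @return class `variogram_fit`: list with `model`, `nugget`, `psill`,
#'   `sill_total`, `range_eff`, `rss`, `r2`, `dd`, `dd_class`, `converged`,
#'   and the fitted `sv`.
#' @export
fit_variogram <- function(sv, model = c("exponential", "spherical", "gaussian"),
                          weights = c("none", "npairs")) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  stopifnot(is.data.frame(sv), all(c("lag", "gamma") %in% names(sv)))
  sv <- sv[is.finite(sv$gamma), , drop = FALSE]
  if (nrow(sv) < 4) stop("need at least 4 non-empty lag bins", call. = FALSE)
  h <- sv$lag
  g <- sv$gamma
  w <- if (weights == "npairs" && !is.null(sv$n_pairs)) sv$n_pairs else rep(1, length(g))

  # Profiled least squares: for a fixed effective range the model is
  # linear in (C0, C), so that subproblem is solved in closed form under
  # the non-negativity constraints; the range is found by a dense
  # log-spaced grid search refined by golden-section. Deterministic, and
  # immune to the spherical model's derivative kink at h = a.
  profile_fit <- function(a) {
    f <- 1 - variogram_correlation(model, h, a)
    sw <- sum(w); swf <- sum(w * f); swff <- sum(w * f * f)
    swg <- sum(w * g); swfg <- sum(w * f * g)
    det <- sw * swff - swf^2
    cands <- list(c(0, if (swff > 0) max(0, swfg / swff) else 0),
                  c(max(0, swg / sw), 0))
    if (det > 1e-12 * max(sw * swff, 1e-300)) {
      C0 <- (swg * swff - swfg * swf) / det
      C <- (sw * swfg - swf * swg) / det
      if (C0 >= 0 && C >= 0) cands <- c(cands, list(c(C0, C)))
    }
    rss <- vapply(cands, function(p) sum(w * (g - p[1] - p[2] * f)^2), 0)
    i <- which.min(rss)
    list(rss = rss[i], par = cands[[i]])
  }
  hmax <- max(h)
  agrid <- exp(seq(log(hmax * 0.02), log(hmax * 4), length.out = 160))
  rss_grid <- vapply(agrid, function(a) profile_fit(a)$rss, 0)
  i_best <- which.min(rss_grid)
  bracket <- c(agrid[max(1, i_best - 1)],
               agrid[min(length(agrid), i_best + 1)])
  opt <- stats::optimize(function(a) profile_fit(a)$rss,
                         interval = bracket, tol = hmax * 1e-9)
  a_hat <- if (opt$objective <= rss_grid[i_best]) opt$minimum else agrid[i_best]
  pf <- profile_fit(a_hat)
  par <- c(pf$par, a_hat)
  converged <- TRUE
  rss <- pf$rss
  tss <- sum(w * (g - sum(w * g) / sum(w))^2)
  r2 <- if (tss > 0) max(0, 1 - rss / tss) else NA_real_
  sill_total <- par[1] + par[2]
  dd <- spatial_dependence(par[1], sill_total)
  structure(list(model = model, nugget = par[1], psill = par[2],
                 sill_total = sill_total, range_eff = par[3],
                 rss = rss, r2 = r2, dd = dd$dd, dd_class = dd$dd_class,
                 converged = converged, weights = weights, sv = sv,
                 n_bins = nrow(sv)),
            class = "variogram_fit")
}

#' Fit all three variogram models and select the best
#'
#' Fits the exponential, spherical and Gaussian models and selects by
#' minimum RSS, breaking near-ties (relative RSS difference below 1e-9)
#' by maximum r-squared and then by model order
#' exponential < spherical < gaussian.
#'
#' @inheritParams fit_variogram
#' @return `fit_variogram_models`: named list of `variogram_fit` objects
#'   (failed fits are dropped with a warning). `select_best_model`: the
#'   winning `variogram_fit`.
#' @export
fit_variogram_models <- function(sv, weights = c("none", "npairs")) {
  weights <- match.arg(weights)
  models <- c("exponential", "spherical", "gaussian")
  fits <- list()
  for (m in models) {
    f <- tryCatch(fit_variogram(sv, m, weights), error = function(e) {
      warning("model ", m, " failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(f)) fits[[m]] <- f
  }
  if (length(fits) == 0) stop("no variogram model converged", call. = FALSE)
  fits
}

#' @param fits list of `variogram_fit` objects (see [fit_variogram_models()]).
#' @rdname fit_variogram_models
#' @export
select_best_model <- function(fits) {
  if (inherits(fits, "variogram_fit")) fits <- list(fits)
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0) stop("no converged variogram fits", call. = FALSE)
  order_rank <- c(exponential = 1, spherical = 2, gaussian = 3)
  rss <- vapply(fits, function(f) f$rss, 0)
  r2 <- vapply(fits, function(f) f$r2, 0)
  mo <- order_rank[vapply(fits, function(f) f$model, "")]
  best_rss <- min(rss)
  tied <- rss <= best_rss + 1e-9 * max(best_rss, 1e-300)
  cand <- which(tied)
  cand <- cand[r2[cand] >= max(r2[cand]) - 1e-12]
  cand <- cand[order(mo[cand])]
  fits[[cand[1]]]
}

#' Degree of spatial dependence
#'
#' The structural variance expressed as a percentage of the total sill:
#' `DD = 100 (sill_total - nugget) / sill_total`, where `sill_total` is
#' the total sill `C0 + C`. Spatial dependence is classed weak when
#' `DD <= 25`, strong when `DD >= 76`, and moderate in between.
#'
#' @param nugget nugget variance C0 (>= 0).
#' @param sill_total total sill C0 + C (> 0).
#' @return list with `dd` (percent) and `dd_class`
#'   (`"weak"`, `"moderate"`, `"strong"`).
#' @examples
#' spatial_dependence(14400, 212600)  # DD = 93.2, strong
#' @export
spatial_dependence <- function(nugget, sill_total) {
  stopifnot(is.numeric(nugget), is.numeric(sill_total))
  if (sill_total <= 0) stop("total sill must be positive", call. = FALSE)
  if (nugget < 0 || nugget > sill_total + 1e-9 * sill_total)
    stop("nugget must lie in [0, sill_total]", call. = FALSE)
  dd <- 100 * (sill_total - nugget) / sill_total
  cls <- if (dd <= 25) "weak" else if (dd >= 76) "strong" else "moderate"
  list(dd = dd, dd_class = cls)
}

#' @export
print.variogram_fit <- function(x, ...) {
  cat(sprintf("Variogram fit (%s model)%s\n", x$model,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  cat(sprintf("  nugget C0 = %.4g, partial sill C = %.4g, total sill = %.4g\n",
              x$nugget, x$psill, x$sill_total))
  cat(sprintf("  effective range = %.4g m\n", x$range_eff))
  cat(sprintf("  r2 = %.3f, RSS = %.4g\n", x$r2, x$rss))
  cat(sprintf("  degree of spatial dependence DD = %.1f%% (%s)\n",
              x$dd, x$dd_class))
  invisible(x)
}

#' @export
coef.variogram_fit <- function(object, ...) {
  c(nugget = object$nugget, psill = object$psill,
    sill_total = object$sill_total, range_eff = object$range_eff)
}

#' @export
predict.variogram_fit <- function(object, lag = object$sv$lag, ...) {
  variogram_model_curve(object$model, lag, object$nugget, object$psill,
                        object$range_eff)
}

#' @export
residuals.variogram_fit <- function(object, ...) {
  object$sv$gamma - predict(object)
}

#' @export
summary.variogram_fit <- function(object, ...) {
  out <- data.frame(model = object$model, nugget = object$nugget,
                    sill = object$sill_total, dd = object$dd,
                    dd_class = object$dd_class, range_m = object$range_eff,
                    r2 = object$r2, rss = object$rss,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
plot.variogram_fit <- function(x, ...) {
  plot(x$sv$lag, x$sv$gamma, xlab = "lag distance (m)",
       ylab = expression(gamma(h)), pch = 16,
       ylim = c(0, max(x$sv$gamma, x$sill_total) * 1.05), ...)
  hh <- seq(0, max(x$sv$lag), length.out = 200)
  graphics::lines(hh, predict(x, hh), col = "steelblue", lwd = 2)
  graphics::abline(h = x$sill_total, lty = 3)
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("%s: DD = %.1f%% (%s)", x$model, x$dd, x$dd_class))
  invisible(x)
}

#' @export
plot.semivariogram <- function(x, ...) {
  plot(x$lag, x$gamma, xlab = "lag distance (m)", ylab = expression(gamma(h)),
       pch = 16, ...)
  invisible(x)
}
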