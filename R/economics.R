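#' Survey cost and time parameters
#'
#' Bundles the parameters of the aerial-versus-ground survey economics
#' model. Defaults reproduce the reference survey: a 0.5-h pre-flight
#' check, 0.05 flight hours per block, image analysis of 2 h over 31
#' blocks (0.0645 h/block), USD 50/h expert fee, USD 100/h technology fee
#' (drone plus software rental), and a ground crew of 19 surveyors who
#' covered 45 blocks in 1.1 h each at USD 10/h, i.e. 0.4644 person-hours
#' per block.
#'
#' @param t_preflight pre-flight check time, hours per mission.
#' @param t_flight_per_block flight hours per block.
#' @param analysis_hours_total,analysis_blocks total image-analysis hours
#'   and the block count they covered; their ratio is the per-block
#'   analysis time (`t_analysis_per_block` overrides it if given).
#' @param t_analysis_per_block image analysis hours per block (optional).
#' @param f_expert expert (pilot/analyst) fee, USD per hour.
#' @param f_technology technology fee, USD per hour.
#' @param f_labor ground surveyor fee, USD per hour per surveyor.
#' @param n_surveyors ground crew size.
#' @param ground_hours_per_surveyor hours each surveyor worked.
#' @param blocks_ground_surveyed blocks the ground crew covered.
#' @return list of class `survey_cost_params`; includes the derived
#'   `ground_person_hours_per_block`.
#' @examples
#' p <- survey_cost_params()
#' round(p$t_analysis_per_block, 4)  # 0.0645
#' @export
survey_cost_params <- function(t_preflight = 0.5, t_flight_per_block = 0.05,
                               analysis_hours_total = 2, analysis_blocks = 31,
                               t_analysis_per_block = NULL,
                               f_expert = 50, f_technology = 100,
                               f_labor = 10, n_surveyors = 19,
                               ground_hours_per_surveyor = 1.1,
                               blocks_ground_surveyed = 45) {
  if (is.null(t_analysis_per_block))
    t_analysis_per_block <- analysis_hours_total / analysis_blocks
  p <- list(t_preflight = t_preflight,
            t_flight_per_block = t_flight_per_block,
            t_analysis_per_block = t_analysis_per_block,
            f_expert = f_expert, f_technology = f_technology,
            f_labor = f_labor, n_surveyors = n_surveyors,
            ground_hours_per_surveyor = ground_hours_per_surveyor,
            blocks_ground_surveyed = blocks_ground_surveyed)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1 || x < 0, TRUE)))
    stop("all survey cost parameters must be non-negative scalars", call. = FALSE)
  if (p$blocks_ground_surveyed <= 0)
    stop("blocks_ground_surveyed must be positive", call. = FALSE)
  p$ground_person_hours_per_block <-
    p$n_surveyors * p$ground_hours_per_surveyor / p$blocks_ground_surveyed
  class(p) <- "survey_cost_params"
  p
}

#' Aerial survey time and cost
#'
#' Total drone operation time is `T_UAS = t_preflight +
#' t_flight_per_block * N` and analysis time `T_analysis =
#' t_analysis_per_block * N`; total cost is
#' `(T_UAS + T_analysis) * (F_expert + F_technology)` and per-block cost
#' divides by `N`. The per-block cost decreases with `N` as the fixed
#' pre-flight time is amortized.
#'
#' @param params a [survey_cost_params()].
#' @param N number of blocks surveyed (vectorized, each >= 1).
#' @return data frame with `N`, `hours` (total person-hours),
#'   `total_cost`, `per_block_cost` (USD).
#' @export
aerial_cost <- function(params, N) {
  stopifnot(inherits(params, "survey_cost_params"))
  if (any(N < 1)) stop("N must be at least 1", call. = FALSE)
  t_uas <- params$t_preflight + params$t_flight_per_block * N
  t_analysis <- params$t_analysis_per_block * N
  hours <- t_uas + t_analysis
  total <- hours * (params$f_expert + params$f_technology)
  data.frame(N = N, hours = hours, total_cost = total,
             per_block_cost = total / N)
}

#' Ground survey time and cost
#'
#' Ground person-hours scale linearly with the number of blocks at the
#' observed per-block rate (`n_surveyors * ground_hours_per_surveyor /
#' blocks_ground_surveyed`); cost is `F_labor` times person-hours.
#'
#' @inheritParams aerial_cost
#' @return data frame with `N`, `hours` (total person-hours),
#'   `total_cost`, `per_block_cost` (USD).
#' @export
ground_cost <- function(params, N) {
  stopifnot(inherits(params, "survey_cost_params"))
  if (any(N < 1)) stop("N must be at least 1", call. = FALSE)
  hours <- params$ground_person_hours_per_block * N
  total <- params$f_labor * hours
  data.frame(N = N, hours = hours, total_cost = total,
             per_block_cost = total / N)
}

#' Breakeven block count for the aerial survey
#'
#' Scans `N = 1..N_max` and returns the smallest block count at which the
#' aerial survey's total person-hours (`mode = "time"`) or total cost
#' (`mode = "cost"`) is no greater than the ground survey's, together with
#' the full comparison profile. Both totals are linear in `N`, so a
#' crossing, when it exists, is unique. With the default parameters the
#' time comparison crosses at `N = 2` (the aerial survey wins whenever
#' more than one block is surveyed), while the cost curves never cross
#' because the aerial cost slope exceeds the ground cost slope.
#'
#' @param params a [survey_cost_params()].
#' @param mode `"time"` or `"cost"`.
#' @param N_max largest block count scanned (default 100).
#' @return list with `breakeven_N` (integer, or `NA` when the aerial
#'   survey never catches up within `N_max`) and `profile`, a data frame
#'   of `N`, `aerial`, `ground`, and `gap = aerial - ground`.
#' @examples
#' breakeven(survey_cost_params(), "time")$breakeven_N  # 2
#' @export
breakeven <- function(params, mode = c("time", "cost"), N_max = 100) {
  mode <- match.arg(mode)
  stopifnot(N_max >= 1)
  N <- seq_len(N_max)
  a <- aerial_cost(params, N)
  g <- ground_cost(params, N)
  av <- if (mode == "time") a$hours else a$total_cost
  gv <- if (mode == "time") g$hours else g$total_cost
  ok <- which(av <= gv)
  list(breakeven_N = if (length(ok)) ok[1] else NA_integer_,
       mode = mode,
       profile = data.frame(N = N, aerial = av, ground = gv, gap = av - gv))
}

#' Survey comparison curves
#'
#' Time and cost of aerial and ground surveys over a range of block
#' counts, in long-friendly wide format for export or plotting.
#'
#' @param params a [survey_cost_params()].
#' @param N_max largest block count (default 50).
#' @return data frame with `N`, `aerial_hours`, `ground_hours`,
#'   `aerial_cost`, `ground_cost`.
#' @export
survey_cost_curves <- function(params, N_max = 50) {
  N <- seq_len(N_max)
  a <- aerial_cost(params, N)
  g <- ground_cost(params, N)
  data.frame(N = N, aerial_hours = a$hours, ground_hours = g$hours,
             aerial_cost = a$total_cost, ground_cost = g$total_cost)
}
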