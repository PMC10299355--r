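#' Default pipeline configuration
#'
#' Returns the full configuration tree for [run_pipeline()] with every
#' stage enabled. The synthetic scene defaults describe one outbreak-style
#' study area: a 24 x 24 lattice of 54-m cells split into a 2 x 2 layout
#' of rectangular blocks, an exponential damage variogram with 80%
#' structural variance (nugget 0.2, partial sill 0.8 on the Gaussian
#' scale) and a 540-m effective range, rendered at 10 px per cell edge.
#'
#' @return nested named list of stage settings.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    simulate = list(enabled = TRUE,
                    n_rows = 24, n_cols = 24, cell_size = 54,
                    block_rows = 2, block_cols = 2,
                    model = "exponential", nugget = 0.2, partial_sill = 0.8,
                    range_eff = 540, lo = 0, hi = 1,
                    px_per_side = 10, jitter = 10,
                    ndvi_healthy = 0.8, ndvi_damaged = 0.2,
                    ndvi_noise_sd = 0.01, regrowth_fraction = 0.5,
                    damaged_cell_cutoff = 0.5),
    defoliate = list(enabled = TRUE, threshold = 20, pixel_area_m2 = 0.02),
    grid = list(enabled = TRUE, cell_size = 54),
    variogram = list(enabled = TRUE, n_bins = 12, max_lag = NULL,
                     max_defoliation = 95),
    sadie = list(enabled = TRUE, K = 999, max_defoliation = 95),
    ndvi = list(enabled = TRUE, threshold = 0.05),
    econ = list(enabled = TRUE, N_max = 50)
  )
}

# Merge a user config into the defaults, rejecting unknown keys at every
# level so typos fail loudly instead of silently running defaults.
merge_config <- function(user, defaults, path = "config") {
  if (is.null(user)) return(defaults)
  stopifnot(is.list(user))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(user[[k]], defaults[[k]],
                                    paste0(path, "$", k))
    } else {
      defaults[k] <- user[k]
    }
  }
  defaults
}

#' Read a pipeline configuration file
#'
#' JSON (or YAML, when the `yaml` package is installed) configuration,
#' validated against [default_pipeline_config()]: unknown keys are
#' rejected.
#'
#' @param path file path (`.json`, `.yaml`/`.yml`).
#' @return complete configuration list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  merge_config(user, default_pipeline_config())
}

block_polygons <- function(grid, block_rows, block_cols) {
  stopifnot(grid$n_rows %% block_rows == 0, grid$n_cols %% block_cols == 0)
  cs <- grid$cell_size
  bh <- grid$n_rows / block_rows * cs
  bw <- grid$n_cols / block_cols * cs
  blocks <- list()
  for (br in seq_len(block_rows)) {
    for (bc in seq_len(block_cols)) {
      x0 <- grid$origin_xy[1] + (bc - 1) * bw
      y0 <- grid$origin_xy[2] + (br - 1) * bh
      blocks[[sprintf("block_%d", (br - 1) * block_cols + bc)]] <-
        rbind(c(x0, y0), c(x0 + bw, y0), c(x0 + bw, y0 + bh), c(x0, y0 + bh))
    }
  }
  blocks
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order — simulate a scene,
#' quantify defoliation per block, aggregate grid counts, fit
#' semivariograms and the degree of spatial dependence, run SADIE, detect
#' NDVI change, and evaluate survey economics — writing every product
#' under `out_dir` and returning a manifest. All stochastic stages are
#' seeded from `config$seed`, so a rerun with the same configuration
#' reproduces every output file byte for byte (the manifest's timings and
#' timestamp differ).
#'
#' @param config partial configuration list or a path to a JSON/YAML
#'   config; merged over [default_pipeline_config()], unknown keys
#'   rejected.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return the manifest (also written as `manifest.json`): per-stage file
#'   lists, seeds, timings, and the package version.
#' @examples
#' \donttest{
#' man <- run_pipeline(list(sadie = list(K = 99)), out_dir = tempfile())
#' names(man$stages)
#' }
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  else config <- merge_config(config, default_pipeline_config())
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (is.null(config$out_dir)) stop("an output directory is required", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- function(...) file.path(config$out_dir, ...)

  manifest <- list(package = "defolmap",
                   version = as.character(utils::packageVersion("defolmap")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = config$seed, stages = list())
  add_stage <- function(name, files, t0, extra = list()) {
    manifest$stages[[name]] <<- c(list(files = basename(files),
                                       elapsed_s = round(as.numeric(Sys.time()) - t0, 3)),
                                  extra)
  }

  scene <- NULL; blocks <- NULL; triplet <- NULL
  sim <- config$simulate
  if (isTRUE(sim$enabled)) {
    t0 <- as.numeric(Sys.time())
    grid <- grid_spec(cell_size = sim$cell_size, n_rows = sim$n_rows,
                      n_cols = sim$n_cols)
    params <- variogram_params(sim$model, sim$nugget, sim$partial_sill,
                               sim$range_eff)
    field <- generate_damage_field(params, grid, seed = config$seed,
                                   lo = sim$lo, hi = sim$hi)
    scene <- render_scene(field, grid, px_per_side = sim$px_per_side,
                          jitter = sim$jitter, seed = config$seed + 1)
    blocks <- block_polygons(grid, sim$block_rows, sim$block_cols)
    damaged_cells <- scene$realized_fraction > sim$damaged_cell_cutoff
    triplet <- generate_ndvi_triplet(damaged_cells,
                                     ndvi_healthy = sim$ndvi_healthy,
                                     ndvi_damaged = sim$ndvi_damaged,
                                     noise_sd = sim$ndvi_noise_sd,
                                     regrowth_fraction = sim$regrowth_fraction,
                                     seed = config$seed + 2)
    files <- c(od("scene.png"), od("truth_mask.png"), od("blocks.geojson"))
    write_raster_png(scene$rgb, files[1], grid$origin_xy, scene$pixel_size_m)
    write_raster_png(scene$truth_mask, files[2], grid$origin_xy,
                     scene$pixel_size_m)
    write_blocks_geojson(blocks, files[3])
    add_stage("simulate", c(files, paste0(files[1:2], ".json")), t0,
              list(seed = config$seed))
  }

  reports <- NULL; defol_mask <- NULL
  if (isTRUE(config$defoliate$enabled)) {
    if (is.null(scene)) stop("defoliate stage needs a simulated scene", call. = FALSE)
    t0 <- as.numeric(Sys.time())
    H <- nrow(scene$truth_mask); W <- ncol(scene$truth_mask)
    px <- scene$origin_xy[1] + (rep(seq_len(W), each = H) - 0.5) * scene$pixel_size_m
    py <- scene$origin_xy[2] + (rep(seq_len(H), times = W) - 0.5) * scene$pixel_size_m
    block_masks <- lapply(blocks, function(poly)
      matrix(point_in_polygon(px, py, poly), nrow = H))
    greens <- lapply(block_masks, function(bm)
      classify_green(scene$rgb, config$defoliate$threshold, bm))
    ref <- reference_green_fraction(
      vapply(greens, function(g) g$n_green / g$n_total, 0))
    reports <- do.call(rbind, lapply(names(greens), function(id)
      estimate_block_defoliation(greens[[id]], ref, block_id = id,
                                 pixel_area_m2 = config$defoliate$pixel_area_m2)))
    full_green <- classify_green(scene$rgb, config$defoliate$threshold)
    defol_mask <- !full_green$mask
    study <- aggregate_reports(reports)
    files <- c(od("defoliation.csv"), od("defoliation_summary.json"))
    write.csv(reports, files[1], row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(n_blocks = study$n_blocks, planted_area_ha = study$planted_area_ha,
           defoliated_area_ha = study$defoliated_area_ha,
           overall_defoliation_pct = study$overall_defoliation_pct,
           category_counts = as.list(study$category_counts),
           reference_green_fraction = ref),
      files[2], auto_unbox = TRUE, digits = NA)
    add_stage("defoliate", files, t0)
  }

  counts_by_block <- NULL
  if (isTRUE(config$grid$enabled)) {
    if (is.null(defol_mask)) stop("grid stage needs the defoliation stage", call. = FALSE)
    t0 <- as.numeric(Sys.time())
    files <- character(0)
    counts_by_block <- list()
    for (id in names(blocks)) {
      g <- make_grid(blocks[[id]], config$grid$cell_size)
      gc <- count_damage_per_cell(defol_mask, g$grid,
                                  pixel_size = scene$pixel_size_m,
                                  raster_origin = scene$origin_xy,
                                  polygon = blocks[[id]], keep = g$keep,
                                  block_id = id)
      counts_by_block[[id]] <- gc
      f <- od(sprintf("counts_%s.csv", id))
      write_grid_counts(gc, f)
      files <- c(files, f)
    }
    add_stage("grid", files, t0)
  }

  spatial_ids <- function(maxdef) {
    if (is.null(reports)) names(counts_by_block)
    else filter_spatial_blocks(reports, maxdef)$block_id
  }

  if (isTRUE(config$variogram$enabled)) {
    if (is.null(counts_by_block)) stop("variogram stage needs grid counts", call. = FALSE)
    t0 <- as.numeric(Sys.time())
    rows <- list()
    for (id in intersect(spatial_ids(config$variogram$max_defoliation),
                         names(counts_by_block))) {
      sv <- empirical_semivariogram(counts_by_block[[id]],
                                    n_bins = config$variogram$n_bins,
                                    max_lag = config$variogram$max_lag)
      best <- select_best_model(fit_variogram_models(sv))
      rows[[id]] <- cbind(block_id = id, summary(best))
    }
    f <- od("variogram.csv")
    write.csv(do.call(rbind, rows), f, row.names = FALSE, quote = FALSE)
    add_stage("variogram", f, t0)
  }

  if (isTRUE(config$sadie$enabled)) {
    if (is.null(counts_by_block)) stop("sadie stage needs grid counts", call. = FALSE)
    t0 <- as.numeric(Sys.time())
    rows <- list()
    for (id in intersect(spatial_ids(config$sadie$max_defoliation),
                         names(counts_by_block))) {
      s <- sadie(counts_by_block[[id]], K = config$sadie$K,
                 seed = config$seed + 3)
      rows[[id]] <- cbind(block_id = id, summary(s))
    }
    f <- od("sadie.csv")
    write.csv(do.call(rbind, rows), f, row.names = FALSE, quote = FALSE)
    add_stage("sadie", f, t0, list(K = config$sadie$K, seed = config$seed + 3))
  }

  if (isTRUE(config$ndvi$enabled)) {
    if (is.null(triplet)) stop("ndvi stage needs a simulated triplet", call. = FALSE)
    t0 <- as.numeric(Sys.time())
    res <- ndvi_change_analysis(triplet, config$ndvi$threshold)
    f <- od("ndvi_summary.json")
    jsonlite::write_json(res$summary, f, auto_unbox = TRUE, digits = NA)
    add_stage("ndvi", f, t0)
  }

  if (isTRUE(config$econ$enabled)) {
    t0 <- as.numeric(Sys.time())
    params <- survey_cost_params()
    curves <- survey_cost_curves(params, config$econ$N_max)
    be_t <- breakeven(params, "time", config$econ$N_max)
    be_c <- breakeven(params, "cost", config$econ$N_max)
    files <- c(od("economics.csv"), od("breakeven.json"))
    write.csv(curves, files[1], row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(time_breakeven_N = be_t$breakeven_N,
                              cost_breakeven_N = be_c$breakeven_N),
                         files[2], auto_unbox = TRUE, digits = NA, na = "null")
    add_stage("econ", files, t0)
  }

  jsonlite::write_json(manifest, od("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(manifest)
}
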