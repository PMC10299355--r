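#' Build the cell lattice covering a block polygon
#'
#' Lays a square-cell lattice over the polygon's bounding box, anchored at
#' the bounding box's lower-left corner, and drops cells that have zero
#' area overlap with the polygon. Partially overlapping edge cells are
#' kept (only their in-block pixels are counted later).
#'
#' @param polygon two-column matrix of block vertices (meters), simple
#'   (non-self-intersecting) ring, closed or open.
#' @param cell_size cell edge in meters (default 54).
#' @return list with the covering [grid_spec()] (`grid`) and `keep`, a
#'   logical `n_rows x n_cols` matrix marking cells overlapping the block.
#' @examples
#' sq <- rbind(c(0, 0), c(108, 0), c(108, 108), c(0, 108))
#' g <- make_grid(sq, 54)
#' sum(g$keep)  # 4 cells
#' @export
make_grid <- function(polygon, cell_size = 54) {
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a positive number", call. = FALSE)
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L || polygon_area(polygon) <= 0)
    stop("degenerate block polygon", call. = FALSE)
  x0 <- min(polygon[, 1]); x1 <- max(polygon[, 1])
  y0 <- min(polygon[, 2]); y1 <- max(polygon[, 2])
  n_cols <- max(1L, ceiling((x1 - x0) / cell_size - 1e-9))
  n_rows <- max(1L, ceiling((y1 - y0) / cell_size - 1e-9))
  grid <- grid_spec(origin_xy = c(x0, y0), cell_size = cell_size,
                    n_rows = n_rows, n_cols = n_cols)
  keep <- matrix(FALSE, n_rows, n_cols)
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      keep[r, c] <- rect_overlaps_polygon(
        x0 + (c - 1) * cell_size, x0 + c * cell_size,
        y0 + (r - 1) * cell_size, y0 + r * cell_size, polygon)
    }
  }
  list(grid = grid, keep = keep)
}

#' Count defoliated pixels per grid cell
#'
#' Assigns every defoliated pixel to the cell containing its center
#' (pixels whose center falls exactly on a cell boundary go to the cell
#' with the smaller row/column index) and, optionally, restricts counting
#' to pixels inside the block polygon. The assignment is a partition, so
#' cell counts sum exactly to the number of in-scope defoliated pixels.
#'
#' @param mask logical matrix of defoliated pixels; row 1 is the
#'   southernmost pixel row (y grows with row index).
#' @param grid a [grid_spec()] (typically from [make_grid()]).
#' @param raster_origin length-2 xy of the raster's lower-left corner in
#'   meters (default: the grid origin).
#' @param pixel_size pixel edge in meters.
#' @param polygon optional block polygon; pixels with centers outside it
#'   are ignored.
#' @param keep optional logical cell matrix from [make_grid()]; cells not
#'   kept are removed from the output.
#' @param block_id block identifier recorded in the output.
#' @return a `grid_counts` data frame with columns `x`, `y` (cell
#'   centroids, meters) and `count`, plus attributes `cell_size` and
#'   `block_id`.
#' @export
count_damage_per_cell <- function(mask, grid, pixel_size,
                                  raster_origin = grid$origin_xy,
                                  polygon = NULL, keep = NULL,
                                  block_id = "block") {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(mask),
            is.numeric(pixel_size), pixel_size > 0)
  idx <- which(mask, arr.ind = TRUE)
  cs <- grid$cell_size
  ext_x <- grid$origin_xy[1] + c(0, grid$n_cols * cs)
  ext_y <- grid$origin_xy[2] + c(0, grid$n_rows * cs)
  counts <- matrix(0L, grid$n_rows, grid$n_cols)
  if (nrow(idx) > 0) {
    px <- raster_origin[1] + (idx[, 2] - 0.5) * pixel_size
    py <- raster_origin[2] + (idx[, 1] - 0.5) * pixel_size
    ok <- px >= ext_x[1] & px <= ext_x[2] & py >= ext_y[1] & py <= ext_y[2]
    if (!all(ok) && is.null(polygon))
      stop("mask extent is not contained in the grid extent", call. = FALSE)
    if (!is.null(polygon))
      ok <- ok & point_in_polygon(px, py, polygon)
    px <- px[ok]; py <- py[ok]
    if (length(px) > 0) {
      # boundary pixels tie toward the lower-index cell: ceiling puts an
      # exact-boundary center in the lower cell since cell c covers
      # ((c-1) cs, c cs]
      col <- pmin(grid$n_cols, pmax(1L, ceiling((px - grid$origin_xy[1]) / cs)))
      row <- pmin(grid$n_rows, pmax(1L, ceiling((py - grid$origin_xy[2]) / cs)))
      tab <- table(factor(row, levels = seq_len(grid$n_rows)),
                   factor(col, levels = seq_len(grid$n_cols)))
      counts <- matrix(as.integer(tab), grid$n_rows, grid$n_cols)
    }
  }
  cen <- grid_centroids(grid)
  out <- data.frame(x = cen$x, y = cen$y,
                    count = as.integer(counts[cbind(cen$row, cen$col)]))
  if (!is.null(keep)) out <- out[keep[cbind(cen$row, cen$col)], , drop = FALSE]
  rownames(out) <- NULL
  grid_counts(out, cell_size = cs, block_id = block_id)
}

#' Construct a grid-counts table
#'
#' @param df data frame with numeric `x`, `y` (meters) and non-negative
#'   integer `count` columns.
#' @param cell_size cell edge in meters.
#' @param block_id block identifier.
#' @return the data frame with class `grid_counts` and the two attributes.
#' @export
grid_counts <- function(df, cell_size = NA_real_, block_id = "block") {
  stopifnot(is.data.frame(df), all(c("x", "y", "count") %in% names(df)))
  if (any(df$count < 0)) stop("counts must be non-negative", call. = FALSE)
  out <- df[, c("x", "y", "count")]
  attr(out, "cell_size") <- cell_size
  attr(out, "block_id") <- block_id
  class(out) <- c("grid_counts", "data.frame")
  out
}

#' Read/write the `x,y,count` exchange format
#'
#' The CSV with header `x,y,count` is the exchange format between the
#' gridding, semivariogram, and SADIE stages.
#'
#' @param counts a `grid_counts` data frame.
#' @param path file path.
#' @return `write_grid_counts` returns `path` invisibly;
#'   `read_grid_counts` returns a `grid_counts` data frame.
#' @export
write_grid_counts <- function(counts, path) {
  write.csv(as.data.frame(counts)[, c("x", "y", "count")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grid_counts
#' @export
read_grid_counts <- function(path) {
  df <- read.csv(path)
  grid_counts(df)
}
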