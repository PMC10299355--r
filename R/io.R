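#' Write and read rasters as PNG with a JSON georeferencing sidecar
#'
#' Rasters are exchanged as plain PNG plus a `<path>.json` sidecar holding
#' the planar georeferencing (origin of the lower-left corner in meters,
#' pixel size). RGB arrays are written as 8-bit color PNG, matrices
#' (masks, single bands in `[0, 1]`) as greyscale. Internally row 1 is the
#' southernmost row; PNG stores north-up, so rows are flipped on the way
#' in and out.
#'
#' @param raster `H x W x 3` array on the 0-255 scale, or an `H x W`
#'   matrix with values in `[0, 1]` (logical masks are written as 0/1).
#' @param path PNG file path.
#' @param origin_xy lower-left corner (meters).
#' @param pixel_size pixel edge (meters).
#' @return `write_raster_png` returns `path` invisibly. `read_raster_png`
#'   returns the array/matrix (8-bit scale restored for RGB) with
#'   attributes `origin_xy` and `pixel_size` when a sidecar is present.
#' @export
write_raster_png <- function(raster, path, origin_xy = c(0, 0), pixel_size = 1) {
  flip <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (length(dim(raster)) == 3L) {
    img <- array(0, dim = dim(raster))
    for (ch in seq_len(dim(raster)[3])) img[, , ch] <- flip(raster[, , ch]) / 255
  } else {
    img <- flip(matrix(as.numeric(raster), nrow(raster)))
  }
  png::writePNG(img, path)
  jsonlite::write_json(list(origin_xy = as.numeric(origin_xy),
                            pixel_size = pixel_size,
                            convention = "row 1 = south, planar meters"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster_png
#' @export
read_raster_png <- function(path) {
  img <- png::readPNG(path)
  flip <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (length(dim(img)) == 3L) {
    out <- array(0, dim = dim(img)[1:3])
    for (ch in seq_len(dim(img)[3])) out[, , ch] <- flip(img[, , ch]) * 255
    out <- round(out)
  } else {
    out <- flip(img)
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "origin_xy") <- meta$origin_xy
    attr(out, "pixel_size") <- meta$pixel_size
  }
  out
}

#' Write and read block polygons as GeoJSON
#'
#' Blocks are simple polygons in planar meter coordinates, one GeoJSON
#' Feature each with a `block_id` property.
#'
#' @param blocks named list of two-column vertex matrices (names are block
#'   ids).
#' @param path GeoJSON file path.
#' @return `write_blocks_geojson` returns `path` invisibly;
#'   `read_blocks_geojson` returns the named list of matrices.
#' @export
write_blocks_geojson <- function(blocks, path) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  ids <- names(blocks)
  if (is.null(ids)) ids <- paste0("block_", seq_along(blocks))
  features <- lapply(seq_along(blocks), function(i) {
    ring <- as.matrix(blocks[[i]])
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         properties = list(block_id = ids[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) ring[k, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_blocks_geojson
#' @export
read_blocks_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopifnot(identical(gj$type, "FeatureCollection"))
  blocks <- list()
  for (f in gj$features) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(unlist(p))))
    id <- f$properties$block_id
    if (is.null(id)) id <- paste0("block_", length(blocks) + 1)
    blocks[[id]] <- ring
  }
  blocks
}
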