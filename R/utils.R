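#' @useDynLib defolmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dist optim pnorm qnorm rnorm runif sd var
#' @importFrom utils read.csv write.csv
NULL

# Run `code` under a local RNG stream started at `seed`, restoring the
# caller's RNG state afterwards: every stochastic operation takes an explicit
# seed and leaves no trace in the global stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Ray-casting point-in-polygon for simple polygons. `poly` is a two-column
# matrix of vertices (closed or open ring). Points exactly on an edge may be
# assigned either way; callers needing exact edge semantics avoid them.
point_in_polygon <- function(x, y, poly) {
  poly <- as.matrix(poly)
  nv <- nrow(poly)
  if (nv >= 2L && all(poly[1L, ] == poly[nv, ])) {
    poly <- poly[-nv, , drop = FALSE]
    nv <- nv - 1L
  }
  if (nv < 3L) stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  inside <- logical(length(x))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# TRUE if axis-aligned rectangle [x0,x1]x[y0,y1] has nonzero-area overlap
# with the polygon (vertex containment either way, or proper edge crossing).
rect_overlaps_polygon <- function(x0, x1, y0, y1, poly) {
  poly <- as.matrix(poly)
  nv <- nrow(poly)
  if (all(poly[1L, ] == poly[nv, ])) {
    poly <- poly[-nv, , drop = FALSE]
    nv <- nv - 1L
  }
  cx <- c(x0, x1, x1, x0)
  cy <- c(y0, y0, y1, y1)
  if (any(point_in_polygon(cx, cy, poly))) return(TRUE)
  mx <- (x0 + x1) / 2; my <- (y0 + y1) / 2
  if (point_in_polygon(mx, my, poly)) return(TRUE)
  if (any(poly[, 1L] > x0 & poly[, 1L] < x1 & poly[, 2L] > y0 & poly[, 2L] < y1))
    return(TRUE)
  rect <- rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    for (k in 1:4) {
      l <- if (k == 4L) 1L else k + 1L
      if (segments_intersect(poly[i, ], poly[j, ], rect[k, ], rect[l, ]))
        return(TRUE)
    }
  }
  FALSE
}

polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  nv <- nrow(poly)
  if (all(poly[1L, ] == poly[nv, ])) poly <- poly[-nv, , drop = FALSE]
  x <- poly[, 1L]; y <- poly[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}
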