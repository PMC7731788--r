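## Small planar-geometry helpers shared by the simulator, the masks and the
## statistics. Polygons are n x 2 matrices with columns (x, y) in micrometres,
## vertices in order, implicitly closed.

#' Regular polygon approximating a circle
#'
#' @param center numeric length-2, circle centre `(x, y)` in µm.
#' @param radius circle radius in µm.
#' @param n number of vertices.
#' @return an `n x 2` matrix of vertices (columns `x`, `y`).
#' @export
circle_polygon <- function(center, radius, n = 72L) {
  stopifnot(length(center) == 2L, radius > 0, n >= 3L)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th))
}

#' Axis-aligned rectangle polygon
#'
#' @param xlim,ylim numeric length-2 ranges in µm.
#' @return a `4 x 2` vertex matrix.
#' @export
rect_polygon <- function(xlim, ylim) {
  cbind(x = c(xlim[1], xlim[2], xlim[2], xlim[1]),
        y = c(ylim[1], ylim[1], ylim[2], ylim[2]))
}

as_polygon <- function(p) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L) stop("a polygon needs an n x 2 matrix with n >= 3")
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y")
  p
}

#' Test points against a polygon
#'
#' @param poly polygon vertex matrix (µm).
#' @param x,y point coordinates (µm), recycled to common length.
#' @return logical vector, `TRUE` where the point lies inside.
#' @export
points_in_polygon <- function(poly, x, y) {
  poly <- as_polygon(poly)
  n <- max(length(x), length(y))
  pts <- cbind(rep_len(as.numeric(x), n), rep_len(as.numeric(y), n))
  mgcv::in.out(rbind(poly, poly[1L, , drop = FALSE]), pts)
}

#' Signed polygon area by the shoelace formula
#' @param poly polygon vertex matrix (µm).
#' @return area in µm² (absolute value).
#' @export
polygon_area <- function(poly) {
  poly <- as_polygon(poly)
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

polygon_bbox <- function(poly) {
  poly <- as_polygon(poly)
  list(xlim = range(poly[, 1]), ylim = range(poly[, 2]))
}

## Deterministic quasi-uniform sample of points inside a polygon: the
## densest square grid with at least n_min interior points.
polygon_grid_points <- function(poly, n_min = 2e4) {
  poly <- as_polygon(poly)
  bb <- polygon_bbox(poly)
  area <- polygon_area(poly)
  if (area <= 0) stop("degenerate region (zero area)")
  h <- sqrt(area / n_min)
  repeat {
    gx <- seq(bb$xlim[1] + h / 2, bb$xlim[2], by = h)
    gy <- seq(bb$ylim[1] + h / 2, bb$ylim[2], by = h)
    g <- expand.grid(x = gx, y = gy)
    keep <- points_in_polygon(poly, g$x, g$y)
    if (sum(keep) >= n_min) return(as.matrix(g[keep, , drop = FALSE]))
    h <- h / sqrt(2)
  }
}

## Uniform random points inside a polygon by rejection from the bounding box,
## drawing from the current RNG stream.
polygon_runif_points <- function(poly, n) {
  poly <- as_polygon(poly)
  if (n == 0L) return(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("x", "y"))))
  bb <- polygon_bbox(poly)
  out <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("x", "y")))
  got <- 0L
  while (got < n) {
    m <- max(2L * (n - got), 16L)
    px <- runif(m, bb$xlim[1], bb$xlim[2])
    py <- runif(m, bb$ylim[1], bb$ylim[2])
    keep <- which(points_in_polygon(poly, px, py))
    take <- head(keep, n - got)
    if (length(take)) {
      out[(got + 1L):(got + length(take)), ] <- cbind(px[take], py[take])
      got <- got + length(take)
    }
  }
  out
}

#' Rasterize a polygon to a pixel mask
#'
#' Pixel `(row r, col c)` (0-based) covers the square
#' `[c, c+1) x [r, r+1)` in pixel units; its centre is at
#' `((c + 0.5) * pixel_size, (r + 0.5) * pixel_size)` µm. A pixel belongs to
#' the mask when its centre lies inside the polygon.
#'
#' @param poly polygon vertex matrix (µm).
#' @param image_shape integer length-2, `(rows, cols)`.
#' @param pixel_size pixel size in µm.
#' @return logical `rows x cols` matrix.
#' @export
polygon_mask <- function(poly, image_shape, pixel_size) {
  nr <- image_shape[1]; nc <- image_shape[2]
  cx <- (seq_len(nc) - 0.5) * pixel_size
  cy <- (seq_len(nr) - 0.5) * pixel_size
  g <- expand.grid(y = cy, x = cx) # column-major: rows vary fastest
  inside <- points_in_polygon(poly, g$x, g$y)
  matrix(inside, nr, nc)
}
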