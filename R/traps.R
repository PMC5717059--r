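# Detector arrays and planar hull geometry. All coordinates are planar km;
# no geodesy is attempted anywhere in the package.

#' Place a regular lattice of camera-trap detectors
#'
#' Builds a rectangular grid of binary proximity detectors (single camera
#' stations; several animals may be detected at one station on one
#' occasion), mimicking pre-mapped survey grids.
#'
#' @param grid_rows,grid_cols Number of rows/columns (each >= 2 for a
#'   two-dimensional array; `grid_cols = 1` is allowed and yields a
#'   degenerate, collinear array).
#' @param spacing_km Distance between adjacent detectors in km (> 0).
#' @param origin Numeric length-2, coordinates of the south-west detector.
#' @param session Session label attached to every detector.
#' @return A `trap_array`: data frame with columns `trap_id`, `x_km`,
#'   `y_km`, `session`.
#' @export
#' @examples
#' tr <- place_traps(8, 8, 1.5)
#' mcp_hull(tr)$area_km2  # 110.25
place_traps <- function(grid_rows, grid_cols, spacing_km, origin = c(0, 0),
                        session = "S1") {
  stopifnot(grid_rows >= 1, grid_cols >= 1, grid_rows * grid_cols >= 2)
  if (!is.numeric(spacing_km) || spacing_km <= 0) {
    stop("`spacing_km` must be a positive number")
  }
  g <- expand.grid(
    col = seq_len(grid_cols) - 1L,
    row = seq_len(grid_rows) - 1L
  )
  out <- data.frame(
    trap_id = sprintf("T%03d", seq_len(nrow(g))),
    x_km = origin[1] + g$col * spacing_km,
    y_km = origin[2] + g$row * spacing_km,
    session = session,
    stringsAsFactors = FALSE
  )
  class(out) <- c("trap_array", "data.frame")
  attr(out, "spacing_km") <- spacing_km
  out
}

#' @noRd
as_trap_matrix <- function(traps) {
  stopifnot(all(c("x_km", "y_km") %in% names(traps)))
  cbind(traps$x_km, traps$y_km)
}

# planar shoelace area of a polygon given as a vertex matrix (not closed)
#' @noRd
polygon_area <- function(v) {
  n <- nrow(v)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])) / 2
}

#' @noRd
polygon_perimeter <- function(v) {
  n <- nrow(v)
  if (n < 2) return(0)
  i2 <- c(2:n, 1)
  sum(sqrt((v[i2, 1] - v[, 1])^2 + (v[i2, 2] - v[, 2])^2))
}

#' Minimum convex polygon around a detector array
#'
#' Convex hull of the detector locations with planar area and perimeter.
#' Fewer than three distinct non-collinear points give a degenerate hull
#' (zero area); the perimeter of a degenerate segment is twice its length,
#' so that the dilation closed form still returns the exact area of the
#' buffered segment.
#'
#' @param traps A `trap_array` or any data frame with `x_km`, `y_km`, or a
#'   two-column coordinate matrix.
#' @return List with `vertices` (matrix, counter-clockwise), `area_km2`,
#'   `perimeter_km`, `degenerate` (logical).
#' @export
mcp_hull <- function(traps) {
  xy <- if (is.matrix(traps)) traps else as_trap_matrix(traps)
  xy <- unique(xy)
  if (nrow(xy) == 1) {
    return(list(vertices = xy, area_km2 = 0, perimeter_km = 0,
                degenerate = TRUE))
  }
  idx <- grDevices::chull(xy[, 1], xy[, 2])
  v <- xy[idx, , drop = FALSE]
  a <- polygon_area(v)
  if (a < 1e-12) {
    # collinear: reduce to the extreme segment; perimeter is out-and-back
    d <- as.matrix(stats::dist(xy))
    ij <- which(d == max(d), arr.ind = TRUE)[1, ]
    v <- xy[ij, , drop = FALSE]
    len <- max(d)
    return(list(vertices = v, area_km2 = 0, perimeter_km = 2 * len,
                degenerate = TRUE))
  }
  list(vertices = v, area_km2 = a, perimeter_km = polygon_perimeter(v),
       degenerate = FALSE)
}

#' Area of a convex region dilated by a buffer
#'
#' For a convex polygon with area A and perimeter P, the Euclidean dilation
#' by b has area exactly A + P b + pi b^2 (Steiner formula). Degenerate
#' hulls are covered by the same formula with A = 0 and P = 2 L.
#'
#' @param area_km2 Hull area.
#' @param perimeter_km Hull perimeter.
#' @param buffer_km Buffer width (>= 0).
#' @return Dilated area in km^2.
#' @export
dilated_area <- function(area_km2, perimeter_km, buffer_km) {
  stopifnot(buffer_km >= 0, area_km2 >= 0, perimeter_km >= 0)
  area_km2 + perimeter_km * buffer_km + pi * buffer_km^2
}

#' Effective area sampled: buffered minimum convex polygon
#'
#' The denominator of a non-spatial capture-recapture density: the convex
#' hull of the detector array dilated by a buffer width, optionally clipped
#' to a habitat polygon (e.g. a land mask). The unclipped area uses the
#' exact Steiner closed form; clipped areas are obtained by grid
#' integration over the clip polygon.
#'
#' @param traps A `trap_array` (or hull from [mcp_hull()]).
#' @param buffer_km Buffer width in km (>= 0).
#' @param clip_region Optional polygon (two-column vertex matrix) to
#'   intersect with; cells of the integration grid default to
#'   `buffer_km / 50`.
#' @return An `effective_area`: list with `mcp_area_km2`, `mcp_perimeter_km`,
#'   `buffer_km`, `area_km2`, `clipped`.
#' @export
#' @examples
#' tr <- place_traps(2, 2, 10)
#' effective_area(tr, 9)$area_km2  # 100 + 40*9 + pi*81 = 714.47
effective_area <- function(traps, buffer_km, clip_region = NULL) {
  hull <- if (is.list(traps) && !is.data.frame(traps) &&
              all(c("vertices", "area_km2") %in% names(traps))) {
    traps
  } else {
    mcp_hull(traps)
  }
  if (buffer_km < 0) stop("`buffer_km` must be >= 0")
  if (is.null(clip_region)) {
    a <- dilated_area(hull$area_km2, hull$perimeter_km, buffer_km)
    clipped <- FALSE
  } else {
    clip_region <- as.matrix(clip_region)
    if (!is.numeric(clip_region) || ncol(clip_region) != 2 ||
        nrow(clip_region) < 3 || polygon_area(clip_region) <= 0) {
      stop("`clip_region` must be a polygon vertex matrix with >= 3 vertices")
    }
    a <- clipped_dilated_area(hull, buffer_km, clip_region)
    clipped <- TRUE
  }
  out <- list(mcp_area_km2 = hull$area_km2,
              mcp_perimeter_km = hull$perimeter_km,
              buffer_km = buffer_km, area_km2 = a, clipped = clipped)
  class(out) <- "effective_area"
  out
}

# point-in-polygon by ray casting (vertex matrix, not closed)
#' @noRd
point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  j <- n
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# squared distance from points to a segment
#' @noRd
dist2_to_segment <- function(px, py, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  l2 <- vx^2 + vy^2
  if (l2 == 0) return((px - a[1])^2 + (py - a[2])^2)
  t <- pmin(1, pmax(0, ((px - a[1]) * vx + (py - a[2]) * vy) / l2))
  (px - (a[1] + t * vx))^2 + (py - (a[2] + t * vy))^2
}

# area of (hull (+) buffer) intersected with clip polygon, by grid counting
#' @noRd
clipped_dilated_area <- function(hull, buffer_km, clip, cell_km = NULL) {
  cell_km <- cell_km %||% max(buffer_km / 50, 0.02)
  xr <- range(clip[, 1]); yr <- range(clip[, 2])
  xs <- seq(xr[1] + cell_km / 2, xr[2], by = cell_km)
  ys <- seq(yr[1] + cell_km / 2, yr[2], by = cell_km)
  g <- expand.grid(x = xs, y = ys)
  keep <- point_in_polygon(g$x, g$y, clip)
  g <- g[keep, , drop = FALSE]
  if (nrow(g) == 0) return(0)
  v <- hull$vertices
  inside <- if (nrow(v) >= 3) point_in_polygon(g$x, g$y, v) else
    rep(FALSE, nrow(g))
  d2 <- rep(Inf, nrow(g))
  n <- nrow(v)
  for (i in seq_len(max(n - (n < 3), 1))) {
    a <- v[i, ]; b <- v[if (i == n) 1 else i + 1, ]
    d2 <- pmin(d2, dist2_to_segment(g$x, g$y, a, b))
  }
  sum(inside | d2 <= buffer_km^2) * cell_km^2
}

#' @export
print.effective_area <- function(x, ...) {
  cat(sprintf(
    "Effective area: MCP %.2f km2 + %.2f km buffer -> %.2f km2%s\n",
    x$mcp_area_km2, x$buffer_km, x$area_km2,
    if (x$clipped) " (clipped)" else ""))
  invisible(x)
}
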