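# Grid conventions used throughout the package:
#   * regular lon/lat lattice, cell-center registration;
#   * cell (row 1, col 1) is the south-west corner cell;
#   * cell centers sit at origin + (index - 0.5) * step;
#   * value matrices are indexed [lat_row, lon_col], row 1 = southernmost;
#   * one 0.01 degree cell is treated as 1 km x 1 km nominally (no latitude
#     correction), matching the small-cell approximation of the analysis.

#' Define a regular lon/lat grid
#'
#' @param lon_origin,lat_origin Coordinates (degrees) of the south-west
#'   corner of the grid (the outer corner of cell `[1, 1]`, not its center).
#' @param step Cell size in degrees; must be positive.
#' @param n_lon,n_lat Number of columns (east-west) and rows (south-north).
#'
#' @return An object of class `ww_grid`.
#' @export
grid_spec <- function(lon_origin, lat_origin, step, n_lon, n_lat) {
  stopifnot(is.numeric(step), step > 0, n_lon >= 1, n_lat >= 1)
  structure(
    list(lon_origin = lon_origin, lat_origin = lat_origin, step = step,
         n_lon = as.integer(n_lon), n_lat = as.integer(n_lat)),
    class = "ww_grid"
  )
}

#' @export
print.ww_grid <- function(x, ...) {
  cat(sprintf("<ww_grid> %d x %d cells, step %g deg, SW corner (%g, %g)\n",
              x$n_lat, x$n_lon, x$step, x$lon_origin, x$lat_origin))
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param spec A [grid_spec()].
#' @return Numeric vector of longitudes (`lon_centers`) or latitudes
#'   (`lat_centers`) of cell centers.
#' @export
lon_centers <- function(spec) {
  spec$lon_origin + (seq_len(spec$n_lon) - 0.5) * spec$step
}

#' @rdname lon_centers
#' @export
lat_centers <- function(spec) {
  spec$lat_origin + (seq_len(spec$n_lat) - 0.5) * spec$step
}

#' Nearest grid cell to a point
#'
#' Ties (a point exactly equidistant to two cell centers, i.e. on a cell
#' boundary) are broken toward the lower index.
#'
#' @param spec A [grid_spec()].
#' @param lon,lat Point coordinates in degrees.
#' @return A list with `row` and `col` (1-based), or `NA` entries if the
#'   point lies outside the grid.
#' @export
nearest_cell <- function(spec, lon, lat) {
  idx1 <- function(f, n) {
    if (is.na(f) || f < 0 || f > n) return(NA_integer_)
    k <- round(f)
    if (abs(f - k) < 1e-9) {
      # on a cell boundary: tie toward the lower cell (or cell 1 at the edge)
      return(as.integer(max(1L, min(n, k))))
    }
    as.integer(min(n, floor(f) + 1))
  }
  list(row = idx1((lat - spec$lat_origin) / spec$step, spec$n_lat),
       col = idx1((lon - spec$lon_origin) / spec$step, spec$n_lon))
}

#' Construct a raster field on a grid
#'
#' Invalid (masked) cells are stored as `NA`; valid cells must be finite.
#'
#' @param spec A [grid_spec()].
#' @param values Numeric matrix of dimension `n_lat x n_lon` (row 1 is the
#'   southernmost row); `NA` marks masked cells.
#' @return An object of class `ww_raster` (list with `spec` and `values`).
#' @export
raster_field <- function(spec, values) {
  stopifnot(inherits(spec, "ww_grid"), is.matrix(values),
            nrow(values) == spec$n_lat, ncol(values) == spec$n_lon)
  if (any(is.infinite(values) | is.nan(values))) {
    stop("raster values must be finite wherever valid (use NA to mask)")
  }
  structure(list(spec = spec, values = values), class = "ww_raster")
}

#' @export
print.ww_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<ww_raster> %d x %d, %.1f%% valid, range [%g, %g]\n",
              nrow(v), ncol(v), 100 * mean(!is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' Extract a square near-facility window from a raster
#'
#' Returns the `(2 * radius_cells + 1)^2` window centered on the cell whose
#' center is nearest to `(lon, lat)`. Cells falling outside the raster are
#' `NA`; a facility near the edge yields a window with an invalid border,
#' not an error. The center cell index is recorded in the `"center"`
#' attribute.
#'
#' @param field A [raster_field()].
#' @param lon,lat Facility coordinates (degrees); must lie inside the grid.
#' @param radius_cells Window radius in cells (>= 1); the default 7
#'   reproduces the ±7-cell (~±7 km) near-facility definition.
#' @return A numeric matrix (rows = south to north, cols = west to east)
#'   with attributes `center` (row/col in the parent raster) and `radius`.
#' @export
extract_window <- function(field, lon, lat, radius_cells = 7) {
  stopifnot(inherits(field, "ww_raster"), radius_cells >= 1)
  spec <- field$spec
  ctr <- nearest_cell(spec, lon, lat)
  if (is.na(ctr$row) || is.na(ctr$col)) {
    stop(sprintf("point (%g, %g) lies outside the raster domain", lon, lat))
  }
  R <- as.integer(radius_cells)
  n <- 2L * R + 1L
  w <- matrix(NA_real_, n, n)
  rows <- ctr$row + (-R:R)
  cols <- ctr$col + (-R:R)
  rok <- which(rows >= 1 & rows <= spec$n_lat)
  cok <- which(cols >= 1 & cols <= spec$n_lon)
  w[rok, cok] <- field$values[rows[rok], cols[cok]]
  attr(w, "center") <- c(row = ctr$row, col = ctr$col)
  attr(w, "radius") <- R
  w
}

# Bilinear sample of a cell-center-registered matrix at arbitrary points.
# Returns NA outside the convex hull of cell centers or where any of the
# four surrounding cells is NA. Vectorized over (lon, lat).
bilinear_point <- function(spec, values, lon, lat) {
  u <- (lon - spec$lon_origin) / spec$step - 0.5   # 0-based center coords
  v <- (lat - spec$lat_origin) / spec$step - 0.5
  out <- rep(NA_real_, length(u))
  j0 <- floor(u); i0 <- floor(v)
  fx <- u - j0; fy <- v - i0
  # allow points exactly on the far edge of the center hull
  hi_x <- j0 == spec$n_lon - 1 & fx == 0
  hi_y <- i0 == spec$n_lat - 1 & fy == 0
  j0[hi_x] <- j0[hi_x] - 1; fx[hi_x] <- 1
  i0[hi_y] <- i0[hi_y] - 1; fy[hi_y] <- 1
  ok <- !is.na(u) & !is.na(v) &
    j0 >= 0 & j0 <= spec$n_lon - 2 & i0 >= 0 & i0 <= spec$n_lat - 2
  if (any(ok)) {
    i <- i0[ok] + 1L; j <- j0[ok] + 1L
    wx <- fx[ok]; wy <- fy[ok]
    v00 <- values[cbind(i, j)];         v01 <- values[cbind(i, j + 1L)]
    v10 <- values[cbind(i + 1L, j)];    v11 <- values[cbind(i + 1L, j + 1L)]
    out[ok] <- (1 - wy) * ((1 - wx) * v00 + wx * v01) +
      wy * ((1 - wx) * v10 + wx * v11)
  }
  out
}

#' Bilinearly interpolate a coarse raster onto a fine grid
#'
#' Standard bilinear interpolation of cell-center values. Output cells are
#' valid only where all four surrounding coarse cells are valid; fine cells
#' outside the coarse center hull are masked, not an error.
#'
#' @param coarse_field A [raster_field()] on the coarse grid.
#' @param fine_grid A [grid_spec()] describing the target grid.
#' @return A [raster_field()] on `fine_grid`.
#' @export
bilinear_to_fine <- function(coarse_field, fine_grid) {
  stopifnot(inherits(coarse_field, "ww_raster"), inherits(fine_grid, "ww_grid"))
  cs <- coarse_field$spec
  u <- (lon_centers(fine_grid) - cs$lon_origin) / cs$step - 0.5
  v <- (lat_centers(fine_grid) - cs$lat_origin) / cs$step - 0.5
  j0 <- floor(u); i0 <- floor(v)
  fx <- u - j0; fy <- v - i0
  hi_x <- j0 == cs$n_lon - 1 & fx == 0
  hi_y <- i0 == cs$n_lat - 1 & fy == 0
  j0[hi_x] <- j0[hi_x] - 1; fx[hi_x] <- 1
  i0[hi_y] <- i0[hi_y] - 1; fy[hi_y] <- 1
  okx <- j0 >= 0 & j0 <= cs$n_lon - 2
  oky <- i0 >= 0 & i0 <= cs$n_lat - 2
  # clamp indices so matrix subscripting stays legal; mask afterwards
  j0c <- pmin(pmax(j0, 0), cs$n_lon - 2) + 1L
  i0c <- pmin(pmax(i0, 0), cs$n_lat - 2) + 1L
  V <- coarse_field$values
  w00 <- outer(1 - fy, 1 - fx); w01 <- outer(1 - fy, fx)
  w10 <- outer(fy, 1 - fx);     w11 <- outer(fy, fx)
  out <- w00 * V[i0c, j0c, drop = FALSE] + w01 * V[i0c, j0c + 1L, drop = FALSE] +
    w10 * V[i0c + 1L, j0c, drop = FALSE] + w11 * V[i0c + 1L, j0c + 1L, drop = FALSE]
  out[!oky, ] <- NA_real_
  out[, !okx] <- NA_real_
  raster_field(fine_grid, out)
}

# --- footprint oversampling ------------------------------------------------

# Sutherland-Hodgman clip of a polygon against one half-plane.
clip_halfplane <- function(px, py, side, bound) {
  n <- length(px)
  if (n == 0) return(list(x = numeric(0), y = numeric(0)))
  inside <- switch(side,
                   px >= bound, px <= bound, py >= bound, py <= bound)
  ox <- numeric(0); oy <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) { ox <- c(ox, px[i]); oy <- c(oy, py[i]) }
    if (inside[i] != inside[j]) {
      t <- if (side <= 2) (bound - px[i]) / (px[j] - px[i])
           else           (bound - py[i]) / (py[j] - py[i])
      ox <- c(ox, px[i] + t * (px[j] - px[i]))
      oy <- c(oy, py[i] + t * (py[j] - py[i]))
    }
  }
  list(x = ox, y = oy)
}

clip_poly_rect <- function(px, py, x0, x1, y0, y1) {
  p <- list(x = px, y = py)
  p <- clip_halfplane(p$x, p$y, 1L, x0)
  p <- clip_halfplane(p$x, p$y, 2L, x1)
  p <- clip_halfplane(p$x, p$y, 3L, y0)
  clip_halfplane(p$x, p$y, 4L, y1)
}

poly_area <- function(px, py) {
  n <- length(px)
  if (n < 3) return(0)
  abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
}

#' Oversample satellite footprints onto a fine grid
#'
#' Footprints with quality-assurance value below `qa_threshold` are
#' discarded. Each fine cell takes the overlap-area-weighted mean of all
#' retained footprints intersecting it (overlap computed by polygon
#' clipping in the lon/lat plane); cells intersected by no retained
#' footprint are masked. An empty footprint table yields a fully masked
#' field, not an error. The result is invariant to footprint ordering.
#'
#' @param footprints Data frame with quadrilateral corner columns
#'   `lon1..lon4`, `lat1..lat4` (in ring order), a `value` column (trace-gas
#'   column amount) and a `qa` column in `[0, 1]`.
#' @param grid Target [grid_spec()].
#' @param qa_threshold Retain footprints with `qa >= qa_threshold`
#'   (default 0.75, the operational quality cut for tropospheric NO2
#'   retrievals).
#' @return A [raster_field()] on `grid`.
#' @export
oversample <- function(footprints, grid, qa_threshold = 0.75) {
  stopifnot(inherits(grid, "ww_grid"),
            qa_threshold >= 0, qa_threshold <= 1)
  num <- matrix(0, grid$n_lat, grid$n_lon)
  den <- matrix(0, grid$n_lat, grid$n_lon)
  if (!is.null(footprints) && nrow(footprints) > 0) {
    need <- c(paste0("lon", 1:4), paste0("lat", 1:4), "value", "qa")
    stopifnot(all(need %in% names(footprints)))
    if (any(footprints$qa < 0 | footprints$qa > 1)) {
      stop("footprint qa values must lie in [0, 1]")
    }
    keep <- footprints[footprints$qa >= qa_threshold, , drop = FALSE]
    lon_edges <- grid$lon_origin + (0:grid$n_lon) * grid$step
    lat_edges <- grid$lat_origin + (0:grid$n_lat) * grid$step
    for (k in seq_len(nrow(keep))) {
      px <- as.numeric(keep[k, paste0("lon", 1:4)])
      py <- as.numeric(keep[k, paste0("lat", 1:4)])
      if (poly_area(px, py) <= 0) stop("footprint has non-positive area")
      cmin <- max(1L, findInterval(min(px), lon_edges))
      cmax <- min(grid$n_lon, findInterval(max(px), lon_edges, rightmost.closed = TRUE))
      rmin <- max(1L, findInterval(min(py), lat_edges))
      rmax <- min(grid$n_lat, findInterval(max(py), lat_edges, rightmost.closed = TRUE))
      if (cmin > cmax || rmin > rmax) next
      for (r in rmin:rmax) {
        for (cc in cmin:cmax) {
          cl <- clip_poly_rect(px, py, lon_edges[cc], lon_edges[cc + 1],
                               lat_edges[r], lat_edges[r + 1])
          a <- poly_area(cl$x, cl$y)
          if (a > 0) {
            num[r, cc] <- num[r, cc] + a * keep$value[k]
            den[r, cc] <- den[r, cc] + a
          }
        }
      }
    }
  }
  vals <- ifelse(den > 0, num / den, NA_real_)
  raster_field(grid, matrix(vals, grid$n_lat, grid$n_lon))
}
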