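# Wind-aligned compositing of near-facility windows.
#
# Wind-frame convention: the +east (increasing column) axis of a rotated
# window is the DOWNWIND direction, so the leftmost column is the upwind
# orthogonal edge. Flow directions are measured in degrees counter-clockwise
# from grid east (0 deg = flow toward the east, 90 deg = toward the north).

#' Vector-mean wind from hourly components
#'
#' Averages zonal/meridional components as vectors and reports the mean
#' flow direction from the arctangent of the mean components together with
#' the mean-vector speed. If the mean vector has speed at or below
#' `speed_floor` (default 0, i.e. exact cancellation) the sample is flagged
#' calm and the direction is undefined; calm days are dropped from
#' rotation composites.
#'
#' @param u,v Numeric vectors of zonal (east) and meridional (north) wind
#'   components in m/s, one element per hour.
#' @param speed_floor Calm threshold on the mean-vector speed (m/s).
#' @return List with `direction_deg` (in `[0, 360)`, `NA` if calm),
#'   `speed` (m/s) and logical `calm`.
#' @export
vector_mean_wind <- function(u, v, speed_floor = 0) {
  ok <- !is.na(u) & !is.na(v)
  if (!any(ok)) stop("no valid wind hours")
  mu <- mean(u[ok]); mv <- mean(v[ok])
  speed <- sqrt(mu^2 + mv^2)
  calm <- speed <= speed_floor
  dir <- if (calm) NA_real_ else (atan2(mv, mu) * 180 / pi) %% 360
  list(direction_deg = dir, speed = speed, calm = calm)
}

#' Prevailing overpass wind at a facility
#'
#' Bilinearly interpolates the coarse hourly wind fields to the facility
#' location for the satellite-overpass hours and vector-averages them. The
#' default window, hours 16-20 UTC inclusive (five hourly samples), brackets
#' the early-afternoon overpass over the continental U.S.
#'
#' @param winds A wind-field object as returned by
#'   [generate_wind_fields()]: list with `spec` (coarse [grid_spec()]) and
#'   arrays `u`, `v` of dimension `n_lat x n_lon x 24 x n_days`.
#' @param lon,lat Facility coordinates (degrees).
#' @param day Day index.
#' @param hours UTC hours (0-23) to average; default `16:20`.
#' @param speed_floor Calm threshold passed to [vector_mean_wind()].
#' @return As [vector_mean_wind()], plus `day`.
#' @export
prevailing_direction <- function(winds, lon, lat, day, hours = 16:20,
                                 speed_floor = 0) {
  stopifnot(all(hours >= 0), all(hours <= 23))
  hidx <- as.integer(hours) + 1L
  uh <- vapply(hidx, function(h)
    bilinear_point(winds$spec, winds$u[, , h, day], lon, lat), numeric(1))
  vh <- vapply(hidx, function(h)
    bilinear_point(winds$spec, winds$v[, , h, day], lon, lat), numeric(1))
  if (all(is.na(uh) | is.na(vh))) {
    stop(sprintf("no valid wind hours at (%g, %g) on day %d", lon, lat, day))
  }
  res <- vector_mean_wind(uh, vh, speed_floor = speed_floor)
  res$day <- day
  res
}

#' Rotate a buffered window into the wind frame
#'
#' Produces a `(2R+1)^2` window whose +east axis points downwind: each
#' output cell is inverse-mapped through a rotation by `direction_deg`
#' about the center and interpolated from the buffer, so a plume advected
#' along the wind always lands to the right of center. Cells mapping to
#' invalid or out-of-buffer locations become invalid.
#'
#' @param buffer_window Square matrix from [extract_window()] with radius at
#'   least `ceiling(R * sqrt(2))`, so that rotated corners stay covered.
#' @param direction_deg Flow direction (degrees CCW from east).
#' @param R Output window radius in cells.
#' @param method `"bilinear"` (default; invalid cells propagate) or
#'   `"nearest"` (exact for quarter-turn lattice symmetries).
#' @return `(2R+1) x (2R+1)` matrix; rows index crosswind (north in the
#'   wind frame), columns index downwind.
#' @export
rotate_window <- function(buffer_window, direction_deg, R = 7,
                          method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is.matrix(buffer_window),
            nrow(buffer_window) == ncol(buffer_window),
            nrow(buffer_window) %% 2 == 1)
  Rb <- (nrow(buffer_window) - 1L) / 2L
  need <- ceiling(R * sqrt(2))
  if (Rb < need) {
    stop(sprintf("buffer radius %d too small for rotation radius %d; need >= %d",
                 Rb, R, need))
  }
  th <- direction_deg * pi / 180
  n <- 2L * R + 1L
  off <- -R:R
  d <- rep(off, each = n)     # downwind offset (output column)
  cr <- rep(off, times = n)   # crosswind offset (output row)
  e <- d * cos(th) - cr * sin(th)   # source east offset in the buffer
  no <- d * sin(th) + cr * cos(th)  # source north offset
  ctr <- Rb + 1
  if (method == "nearest") {
    ri <- round(no) + ctr; ci <- round(e) + ctr
    vals <- rep(NA_real_, n * n)
    ok <- ri >= 1 & ri <= nrow(buffer_window) & ci >= 1 & ci <= ncol(buffer_window)
    vals[ok] <- buffer_window[cbind(ri[ok], ci[ok])]
  } else {
    r <- no + ctr; cc <- e + ctr
    r0 <- floor(r); c0 <- floor(cc)
    fy <- r - r0; fx <- cc - c0
    hi_r <- r0 == nrow(buffer_window) & fy == 0
    hi_c <- c0 == ncol(buffer_window) & fx == 0
    r0[hi_r] <- r0[hi_r] - 1; fy[hi_r] <- 1
    c0[hi_c] <- c0[hi_c] - 1; fx[hi_c] <- 1
    vals <- rep(NA_real_, n * n)
    ok <- r0 >= 1 & r0 <= nrow(buffer_window) - 1 &
      c0 >= 1 & c0 <= ncol(buffer_window) - 1
    if (any(ok)) {
      B <- buffer_window
      i <- r0[ok]; j <- c0[ok]; wy <- fy[ok]; wx <- fx[ok]
      vals[ok] <- (1 - wy) * ((1 - wx) * B[cbind(i, j)] + wx * B[cbind(i, j + 1)]) +
        wy * ((1 - wx) * B[cbind(i + 1, j)] + wx * B[cbind(i + 1, j + 1)])
    }
  }
  matrix(vals, n, n)   # vals laid out row-major over (cr, d) pairs: col-major (row=cr) OK
}

#' Composite wind-aligned windows
#'
#' Per-cell mean over valid contributions with per-cell contribution
#' counts. Accepts a list of windows (matrices) or of composites (whose
#' `mean` windows are then averaged with equal weight — the second stage of
#' the default two-stage scheme: first daily windows within a facility,
#' then across facilities).
#'
#' @param windows Non-empty list of equal-size square matrices or
#'   `ww_composite` objects.
#' @return Object of class `ww_composite`: list with `mean`, `count`, `R`.
#' @export
composite <- function(windows) {
  if (length(windows) == 0) stop("composite of an empty window list")
  if (inherits(windows[[1]], "ww_composite")) {
    windows <- lapply(windows, `[[`, "mean")
  }
  dims <- vapply(windows, function(w) dim(w)[1], numeric(1))
  if (length(unique(c(dims, vapply(windows, ncol, numeric(1))))) != 1) {
    stop("all windows must share the same radius")
  }
  arr <- array(unlist(windows, use.names = FALSE),
               dim = c(nrow(windows[[1]]), ncol(windows[[1]]), length(windows)))
  cnt <- rowSums(!is.na(arr), dims = 2)
  sm <- rowSums(arr, na.rm = TRUE, dims = 2)
  mn <- ifelse(cnt > 0, sm / cnt, NA_real_)
  structure(list(mean = matrix(mn, nrow(arr), ncol(arr)),
                 count = matrix(cnt, nrow(arr), ncol(arr)),
                 R = (nrow(arr) - 1L) / 2L),
            class = "ww_composite")
}

#' @export
print.ww_composite <- function(x, ...) {
  cat(sprintf("<ww_composite> radius %d, max count %d, mean %.3g\n",
              x$R, max(x$count), mean(x$mean, na.rm = TRUE)))
  invisible(x)
}

#' Upwind-edge enhancement statistic of a composite
#'
#' The enhancement is the relative difference between the composite maximum
#' and the mean over the upwind orthogonal edge (by default the full
#' leftmost column of the wind-aligned window; the edge cell set is
#' configurable). The peak offset is reported in (east = downwind,
#' north = crosswind) cells and the displacement is the downwind component
#' of the offset times the nominal cell size.
#'
#' Because the peak is the window maximum, which can never fall below the
#' mean of any cell subset, the enhancement is always >= 0.
#'
#' @param comp A `ww_composite` or a square matrix.
#' @param edge_cols Column indices forming the upwind edge (default 1).
#' @param edge_rows Row indices of the edge cell set (default all rows).
#' @param cell_km Nominal cell size in km (default 1).
#' @return Object of class `ww_enhancement`: `upwind_edge_mean`,
#'   `peak_value`, `enhancement_pct`, `peak_offset` (east, north cells),
#'   `displacement_km`.
#' @export
enhancement <- function(comp, edge_cols = 1, edge_rows = NULL, cell_km = 1) {
  m <- if (inherits(comp, "ww_composite")) comp$mean else comp
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) %% 2 == 1)
  n <- nrow(m)
  ctr <- (n + 1L) / 2L
  if (is.null(edge_rows)) edge_rows <- seq_len(n)
  edge_vals <- m[edge_rows, edge_cols]
  edge_vals <- edge_vals[!is.na(edge_vals)]
  if (length(edge_vals) == 0) stop("upwind edge is entirely invalid")
  if (all(is.na(m))) stop("composite has no valid cells")
  edge_mean <- mean(edge_vals)
  if (edge_mean <= 0) stop("upwind-edge mean <= 0; relative enhancement undefined")
  mm <- m
  mm[is.na(mm)] <- -Inf
  peak <- max(mm)
  cand <- which(mm == peak)
  ci <- arrayInd(cand, dim(mm))
  # ties broken toward the window center (uniform composite -> zero offset),
  # then toward the lowest linear index
  d2 <- (ci[, 1] - ctr)^2 + (ci[, 2] - ctr)^2
  peak_idx <- ci[which.min(d2), , drop = FALSE]
  structure(list(
    upwind_edge_mean = edge_mean,
    peak_value = peak,
    enhancement_pct = 100 * (peak - edge_mean) / edge_mean,
    peak_offset = c(east = peak_idx[2] - ctr, north = peak_idx[1] - ctr),
    displacement_km = (peak_idx[2] - ctr) * cell_km
  ), class = "ww_enhancement")
}

#' @export
print.ww_enhancement <- function(x, ...) {
  cat(sprintf(paste0("<ww_enhancement> edge %.4g, peak %.4g -> %.1f%% ",
                     "(peak offset %+d east, %+d north; displacement %.1f km)\n"),
              x$upwind_edge_mean, x$peak_value, x$enhancement_pct,
              x$peak_offset["east"], x$peak_offset["north"], x$displacement_km))
  invisible(x)
}

#' Stratified composites and enhancements
#'
#' Builds one composite and enhancement per stratum label over that
#' label's facilities, using the two-stage scheme (per-facility composite
#' across days, then equal-weight average across the stratum's facilities).
#' Strata with zero facilities are omitted with a warning.
#'
#' @param facility_windows List (one element per facility) of lists of
#'   rotated daily windows, or of per-facility `ww_composite`s.
#' @param labels Vector of stratum labels, one per facility (density class,
#'   urban/rural flag, clustering decile, emission-intensity decile,
#'   dominant sector, ...).
#' @param ... Passed to [enhancement()].
#' @return Named list (one per label level) of lists with `composite`,
#'   `enhancement` and `n_facilities`.
#' @export
stratified_enhancement <- function(facility_windows, labels, ...) {
  stopifnot(length(facility_windows) == length(labels))
  fac_comps <- lapply(facility_windows, function(w) {
    if (inherits(w, "ww_composite")) w else composite(w)
  })
  out <- list()
  for (lev in unique(as.character(labels[!is.na(labels)]))) {
    sel <- which(!is.na(labels) & as.character(labels) == lev)
    if (length(sel) == 0) {
      warning(sprintf("stratum '%s' has zero facilities; omitted", lev))
      next
    }
    comp <- composite(fac_comps[sel])
    out[[lev]] <- list(composite = comp,
                       enhancement = enhancement(comp, ...),
                       n_facilities = length(sel))
  }
  if (length(out) == 0) warning("no non-empty strata")
  out
}
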