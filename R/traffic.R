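# Road-segment AADT -> gridded vehicle kilometres travelled (VKT),
# near-facility aggregation, and decile-binned characteristic regressions.
#
# Road segments are straight lon/lat segments stored one per row:
#   id, lon0, lat0, lon1, lat1, length_km, aadt_total, aadt_truck, state
# aadt_truck covers vehicle classes 4-13 (single-unit trucks, buses, semi-
# and multi-trailers); aadt_total covers all classes.

validate_segments <- function(segments) {
  need <- c("lon0", "lat0", "lon1", "lat1", "length_km",
            "aadt_total", "aadt_truck", "state")
  stopifnot(all(need %in% names(segments)))
  if (any(segments$aadt_total < 0 | segments$aadt_truck < 0)) {
    stop("negative AADT")
  }
  if (any(segments$aadt_truck > segments$aadt_total)) {
    stop("truck AADT exceeds total AADT")
  }
  if (any(segments$length_km <= 0)) stop("segment length must be positive")
  invisible(segments)
}

#' Vehicle kilometres travelled of road segments
#'
#' `VKT = AADT x road length`, per class group.
#'
#' @param segments Road-segment data frame (see package conventions).
#' @return `segments` with columns `vkt_total` and `vkt_truck`
#'   (vehicle-km/day) appended.
#' @export
segment_vkt <- function(segments) {
  validate_segments(segments)
  segments$vkt_total <- segments$aadt_total * segments$length_km
  segments$vkt_truck <- segments$aadt_truck * segments$length_km
  segments
}

#' Scale state AADT to reference activity totals
#'
#' Each state's AADT (total and truck alike) is multiplied by the ratio of
#' the reference total VKT for that state to the state's current
#' segment-sum total VKT, so that post-scaling state sums reproduce the
#' reference exactly. With `reference` equal to the current sums the
#' operation is the identity.
#'
#' @param segments Road-segment data frame.
#' @param reference_state_totals Named numeric vector: state code ->
#'   reference total VKT (vehicle-km/day). Every state present in
#'   `segments` must appear.
#' @return The scaled segment table.
#' @export
scale_to_reference <- function(segments, reference_state_totals) {
  validate_segments(segments)
  states <- unique(segments$state)
  missing_states <- setdiff(states, names(reference_state_totals))
  if (length(missing_states) > 0) {
    stop("no reference total for state(s): ",
         paste(missing_states, collapse = ", "))
  }
  cur <- tapply(segments$aadt_total * segments$length_km, segments$state, sum)
  for (s in states) {
    ref <- reference_state_totals[[s]]
    if (cur[[s]] == 0) {
      if (ref != 0) stop(sprintf("state %s has zero segment VKT but nonzero reference", s))
      next
    }
    f <- ref / cur[[s]]
    sel <- segments$state == s
    segments$aadt_total[sel] <- segments$aadt_total[sel] * f
    segments$aadt_truck[sel] <- segments$aadt_truck[sel] * f
  }
  segments
}

#' Rasterize segment VKT onto a grid
#'
#' Each segment's VKT is apportioned to cells by the fraction of its
#' geometric length falling inside each cell (splitting the segment exactly
#' at grid-line crossings), which conserves total VKT under resolution
#' changes. Pieces falling outside the grid are dropped with one warning.
#'
#' @param segments Road-segment data frame.
#' @param grid Target [grid_spec()].
#' @return List with `total` and `truck` [raster_field()]s
#'   (vehicle-km/day per cell; zeros where no road).
#' @export
rasterize_vkt <- function(segments, grid) {
  segments <- segment_vkt(segments)
  tot <- matrix(0, grid$n_lat, grid$n_lon)
  trk <- matrix(0, grid$n_lat, grid$n_lon)
  lon_edges <- grid$lon_origin + (0:grid$n_lon) * grid$step
  lat_edges <- grid$lat_origin + (0:grid$n_lat) * grid$step
  clipped <- FALSE
  for (k in seq_len(nrow(segments))) {
    x0 <- segments$lon0[k]; y0 <- segments$lat0[k]
    x1 <- segments$lon1[k]; y1 <- segments$lat1[k]
    dx <- x1 - x0; dy <- y1 - y0
    ts <- c(0, 1)
    if (dx != 0) {
      t <- (lon_edges - x0) / dx
      ts <- c(ts, t[t > 0 & t < 1])
    }
    if (dy != 0) {
      t <- (lat_edges - y0) / dy
      ts <- c(ts, t[t > 0 & t < 1])
    }
    ts <- sort(unique(ts))
    for (i in seq_len(length(ts) - 1)) {
      frac <- ts[i + 1] - ts[i]
      if (frac <= 0) next
      tm <- (ts[i] + ts[i + 1]) / 2
      mx <- x0 + dx * tm; my <- y0 + dy * tm
      col <- floor((mx - grid$lon_origin) / grid$step) + 1
      row <- floor((my - grid$lat_origin) / grid$step) + 1
      if (col < 1 || col > grid$n_lon || row < 1 || row > grid$n_lat) {
        clipped <- TRUE
        next
      }
      tot[row, col] <- tot[row, col] + frac * segments$vkt_total[k]
      trk[row, col] <- trk[row, col] + frac * segments$vkt_truck[k]
    }
  }
  if (clipped) warning("segment(s) extending outside the grid were clipped")
  list(total = raster_field(grid, tot), truck = raster_field(grid, trk))
}

#' Near-facility traffic sums
#'
#' Sums total and truck VKT over the `(2 radius + 1)^2` cell window around
#' the facility (cells outside the raster contribute zero).
#'
#' @param vkt_fields List with `total` and `truck` rasters from
#'   [rasterize_vkt()].
#' @param lon,lat Facility coordinates.
#' @param radius_cells Window radius (default 7, i.e. a 15 x 15 window).
#' @return List with `total_vkt` and `truck_vkt` (vehicle-km/day).
#' @export
near_facility_traffic <- function(vkt_fields, lon, lat, radius_cells = 7) {
  wt <- extract_window(vkt_fields$total, lon, lat, radius_cells)
  wk <- extract_window(vkt_fields$truck, lon, lat, radius_cells)
  list(total_vkt = sum(wt, na.rm = TRUE), truck_vkt = sum(wk, na.rm = TRUE))
}

#' Decile-binned regression of truck VKT on a facility characteristic
#'
#' Facilities are binned into deciles of near-facility *total* VKT (to
#' control for baseline traffic volume); within each bin, truck VKT is
#' regressed on the characteristic by simple least squares with a
#' two-sided Wald t test. Facilities with a missing characteristic are
#' dropped from that characteristic's regression only. Parking spaces are
#' conventionally fitted scaled by 10 (`scale = 10`) so the slope reads
#' "per 10 parking spaces". Bins with fewer than 3 usable points or zero
#' characteristic variance get an `NA` slope and are flagged.
#'
#' @param facilities Data frame with column `id` and the characteristic.
#' @param near_traffic Data frame `id, total_vkt, truck_vkt` (from
#'   [near_facility_traffic()] per facility).
#' @param characteristic Name of the characteristic column.
#' @param scale Divisor applied to the characteristic before fitting
#'   (default 1).
#' @param n_bins Number of total-VKT bins (default 10).
#' @param alpha Significance threshold (default 0.05).
#' @return Data frame of class `ww_binned_slopes` with one row per bin:
#'   `characteristic, bin, n, slope, se, p, significant, flagged`.
#'   Attributes: `mean_slope` (mean over defined bins), `residuals` (list
#'   per bin, for normality diagnostics), `scale`.
#' @export
decile_bin_regression <- function(facilities, near_traffic, characteristic,
                                  scale = 1, n_bins = 10, alpha = 0.05) {
  stopifnot(characteristic %in% names(facilities),
            all(c("id", "total_vkt", "truck_vkt") %in% names(near_traffic)))
  d <- merge(facilities[, c("id", characteristic)], near_traffic, by = "id")
  d <- d[!is.na(d[[characteristic]]), ]
  if (nrow(d) < n_bins) {
    stop(sprintf("need at least %d facilities with non-missing %s",
                 n_bins, characteristic))
  }
  d$bin <- decile_bins(d$total_vkt, n_bins)
  rows <- list(); resids <- list()
  for (b in seq_len(n_bins)) {
    db <- d[d$bin == b, ]
    x <- db[[characteristic]] / scale
    y <- db$truck_vkt
    if (nrow(db) < 3 || length(unique(x)) < 2) {
      rows[[b]] <- data.frame(characteristic = characteristic, bin = b,
                              n = nrow(db), slope = NA_real_, se = NA_real_,
                              p = NA_real_, significant = NA, flagged = TRUE)
      resids[[b]] <- numeric(0)
      next
    }
    fit <- ols_slope_wald(x, y)
    rows[[b]] <- data.frame(characteristic = characteristic, bin = b,
                            n = fit$n, slope = fit$slope, se = fit$se,
                            p = fit$p, significant = fit$p < alpha,
                            flagged = FALSE)
    resids[[b]] <- fit$residuals
  }
  out <- do.call(rbind, rows)
  attr(out, "mean_slope") <- mean(out$slope, na.rm = TRUE)
  attr(out, "residuals") <- resids
  attr(out, "scale") <- scale
  class(out) <- c("ww_binned_slopes", class(out))
  out
}
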