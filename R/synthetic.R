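# Seeded synthetic scenarios: facilities, tracts, roads, winds, daily NO2
# fields and sectoral emissions, with recorded ground truth so that every
# analysis stage can be verified by parameter recovery.
#
# Each sub-generator draws from its own random stream derived from the
# master seed, so e.g. adding facilities does not perturb the winds.

ww_sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629)
}

#' Scenario configuration
#'
#' Defines one synthetic study region and its generating parameters. The
#' defaults describe the reference scenario used throughout the package's
#' tests: a 1.5 x 1.5 degree domain on a 0.01 degree grid (150 x 150 cells,
#' nominally 1 km each), 225 rectangular tracts, 200 clustered facilities
#' observed over 60 days, plumes displaced 4 km downwind with amplitudes
#' sized so the facility signal is roughly a 20 percent enhancement over
#' background, 30 percent lognormal retrieval noise, and the documented
#' real-world missing-data rates for loading docks (40.7 percent) and
#' parking spaces (31.1 percent).
#'
#' @param domain_bounds Numeric `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param grid_step Fine-grid cell size in degrees (default 0.01; one cell
#'   is treated as 1 km x 1 km nominally).
#' @param tract_cells Tract edge length in cells (default 10; the fine grid
#'   must tile into whole tracts).
#' @param n_facilities Number of facilities (>= 1).
#' @param cluster_intensity Mean facilities per cluster of the clustered
#'   (parent/offspring) point process.
#' @param cluster_sd_km Offspring scatter around cluster parents (km).
#' @param plume_amplitude_per_dock NO2 column units added at the plume peak
#'   per loading dock.
#' @param plume_amplitude_per_cluster Additional amplitude per co-tract
#'   facility (the linear "clustering" term).
#' @param plume_displacement_km Downwind displacement of the plume peak (km).
#' @param plume_sigma_km Isotropic Gaussian plume width (km).
#' @param background_base Background NO2 column level.
#' @param background_density_coeff Background increment per person/km^2.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   retrieval noise (0 disables noise).
#' @param swath_missing_frac Fraction of cells masked per day in `[0, 1)`.
#' @param missing_docks_frac,missing_parking_frac Fractions of facilities
#'   with the characteristic reported missing.
#' @param siting_bias Nonnegative exponent: facility siting probability is
#'   weighted by tract population times `(subgroup share)^siting_bias`; 0
#'   means population-weighted (unbiased) siting.
#' @param siting_subgroup Subgroup whose share drives the siting bias.
#' @param truck_slope_per_dock,truck_slope_per_cluster,truck_slope_per_parking
#'   Structural increments of daily near-facility truck VKT (km) per
#'   loading dock, co-tract facility, and parking space.
#' @param truck_base Baseline truck VKT of a facility access road (km/day).
#' @param truck_noise_sd Noise s.d. of access-road truck VKT (km/day).
#' @param wind_u_mean,wind_v_mean Mean zonal/meridional wind (m/s).
#' @param wind_day_sd,wind_day_rho Day-to-day AR(1) s.d. and coefficient.
#' @param wind_hour_sd,wind_hour_rho Hour-to-hour AR(1) s.d. and coefficient.
#' @param constant_wind Optional `c(u, v)`: force every hourly field to
#'   this constant (degenerate forcing for tests).
#' @param n_days Number of days (>= 1).
#' @param seed Master integer seed.
#' @return Validated list of class `ww_config`.
#' @export
scenario_config <- function(domain_bounds = c(-100, -98.5, 36, 37.5),
                            grid_step = 0.01,
                            tract_cells = 10,
                            n_facilities = 200,
                            cluster_intensity = 4,
                            cluster_sd_km = 3,
                            plume_amplitude_per_dock = 0.06,
                            plume_amplitude_per_cluster = 0.01,
                            plume_displacement_km = 4,
                            plume_sigma_km = 1.5,
                            background_base = 2,
                            background_density_coeff = 5e-4,
                            noise_cv = 0.3,
                            swath_missing_frac = 0.3,
                            missing_docks_frac = 0.407,
                            missing_parking_frac = 0.311,
                            siting_bias = 1,
                            siting_subgroup = "hispanic",
                            truck_slope_per_dock = 1456,
                            truck_slope_per_cluster = 485,
                            truck_slope_per_parking = -13,
                            truck_base = 5000,
                            truck_noise_sd = 2000,
                            wind_u_mean = 2, wind_v_mean = 0.5,
                            wind_day_sd = 2, wind_day_rho = 0.5,
                            wind_hour_sd = 0.8, wind_hour_rho = 0.6,
                            constant_wind = NULL,
                            n_days = 60,
                            seed = 1) {
  cfg <- as.list(environment())
  stopifnot(length(domain_bounds) == 4,
            domain_bounds[2] > domain_bounds[1],
            domain_bounds[4] > domain_bounds[3],
            grid_step > 0, n_days >= 1, n_facilities >= 1,
            cluster_intensity >= 1, siting_bias >= 0,
            plume_sigma_km > 0)
  for (f in c("noise_cv")) stopifnot(cfg[[f]] >= 0)
  for (f in c("swath_missing_frac", "missing_docks_frac",
              "missing_parking_frac")) {
    if (cfg[[f]] < 0 || cfg[[f]] >= 1) {
      stop(sprintf("%s must lie in [0, 1)", f))
    }
  }
  n_lon <- round((domain_bounds[2] - domain_bounds[1]) / grid_step)
  n_lat <- round((domain_bounds[4] - domain_bounds[3]) / grid_step)
  if (n_lon %% tract_cells != 0 || n_lat %% tract_cells != 0) {
    stop("grid must tile into whole tracts (adjust tract_cells)")
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "ww_config")
}

#' Fine analysis grid of a scenario
#' @param config A [scenario_config()].
#' @return A [grid_spec()].
#' @export
grid_from_config <- function(config) {
  b <- config$domain_bounds
  grid_spec(b[1], b[3], config$grid_step,
            round((b[2] - b[1]) / config$grid_step),
            round((b[4] - b[3]) / config$grid_step))
}

coarse_grid_from_config <- function(config, step = 0.25) {
  b <- config$domain_bounds
  grid_spec(b[1] - step, b[3] - step, step,
            ceiling((b[2] - b[1]) / step) + 2,
            ceiling((b[4] - b[3]) / step) + 2)
}

# Smooth latent surfaces (population density and subgroup shares) shared by
# the tract, facility and NO2 generators; parameters are drawn from their
# own seed stream so every generator reconstructs identical surfaces.
ww_surface_params <- function(config) {
  set.seed(ww_sub_seed(config$seed, 11L))
  b <- config$domain_bounds
  mid <- c((b[1] + b[2]) / 2, (b[3] + b[4]) / 2)
  half <- sqrt(((b[2] - b[1]) / 2)^2 + ((b[4] - b[3]) / 2)^2)
  rpt <- function(f) c(runif(1, b[1] + f * (b[2] - b[1]), b[2] - f * (b[2] - b[1])),
                       runif(1, b[3] + f * (b[4] - b[3]), b[4] - f * (b[4] - b[3])))
  runit <- function() { a <- runif(1, 0, 2 * pi); c(cos(a), sin(a)) }
  list(mid = mid, half = half,
       c1 = rpt(0.25), L1 = 0.35, A1 = 3800,
       c2 = rpt(0.15), L2 = 0.25, A2 = 1200, base = 30,
       dir_h = runit(), dir_b = runit(), dir_a = runit(), dir_o = runit())
}

ww_density_at <- function(p, lon, lat) {
  p$base +
    p$A1 * exp(-((lon - p$c1[1])^2 + (lat - p$c1[2])^2) / p$L1^2) +
    p$A2 * exp(-((lon - p$c2[1])^2 + (lat - p$c2[2])^2) / p$L2^2)
}

ww_density_matrix <- function(config) {
  p <- ww_surface_params(config)
  g <- grid_from_config(config)
  lons <- lon_centers(g); lats <- lat_centers(g)
  outer(lats, lons, function(la, lo) ww_density_at(p, lo, la))
}

ww_shares_at <- function(p, lon, lat) {
  proj <- function(dir) ((lon - p$mid[1]) * dir[1] + (lat - p$mid[2]) * dir[2]) / p$half
  h <- plogis(-2.2 + 3.0 * proj(p$dir_h))
  bl <- plogis(-2.4 + 2.5 * proj(p$dir_b))
  a <- plogis(-3.4 + 1.6 * proj(p$dir_a))
  o <- plogis(-2.4 + 1.0 * proj(p$dir_o))
  w <- pmin(0.95, pmax(0.05, 0.92 - 0.75 * h - 0.55 * bl))
  list(hispanic = h, black = bl, asian_nhpi = a, other = o, white = w)
}

tract_index_of <- function(config, lon, lat) {
  b <- config$domain_bounds
  tdeg <- config$grid_step * config$tract_cells
  ntx <- round((b[2] - b[1]) / tdeg)
  nty <- round((b[4] - b[3]) / tdeg)
  tc <- floor((lon - b[1]) / tdeg) + 1
  tr <- floor((lat - b[3]) / tdeg) + 1
  tc <- pmin(pmax(tc, 1), ntx); tr <- pmin(pmax(tr, 1), nty)
  (tr - 1) * ntx + tc
}

#' Generate road segments and census tracts
#'
#' Rectangular tracts tile the domain; each carries an area, a total
#' population integrated from a smooth density surface, and six
#' non-mutually-exclusive subgroup populations whose shares vary smoothly
#' in space (Hispanic + non-Hispanic = total by construction). Roads form a
#' lattice along tract center lines with density-scaled total AADT; when
#' `facilities` is supplied, each facility additionally gets a 1 km access
#' segment whose truck AADT increases with its loading docks and
#' clustering at the configured structural slopes (so with zero facilities
#' the true truck-VKT slope against docks is zero).
#'
#' @param config A [scenario_config()].
#' @param facilities Optional facility table from [generate_facilities()].
#' @return List with `roads` (segment data frame) and `tracts` (tract data
#'   frame; `facility_count` filled from `facilities` if supplied).
#' @export
generate_roads_and_tracts <- function(config, facilities = NULL) {
  p <- ww_surface_params(config)
  b <- config$domain_bounds
  dens <- ww_density_matrix(config)
  tc <- config$tract_cells
  tdeg <- config$grid_step * tc
  ntx <- round((b[2] - b[1]) / tdeg)
  nty <- round((b[4] - b[3]) / tdeg)

  set.seed(ww_sub_seed(config$seed, 1L))
  rows <- vector("list", ntx * nty)
  for (tr in seq_len(nty)) {
    for (tcx in seq_len(ntx)) {
      idx <- (tr - 1) * ntx + tcx
      cell_rows <- ((tr - 1) * tc + 1):(tr * tc)
      cell_cols <- ((tcx - 1) * tc + 1):(tcx * tc)
      pop <- round(sum(dens[cell_rows, cell_cols]) * exp(rnorm(1, 0, 0.1)))
      clon <- b[1] + (tcx - 0.5) * tdeg
      clat <- b[3] + (tr - 0.5) * tdeg
      sh <- ww_shares_at(p, clon, clat)
      jit <- function(s) plogis(qlogis(pmin(pmax(s, 1e-4), 1 - 1e-4)) +
                                  rnorm(1, 0, 0.15))
      h <- round(jit(sh$hispanic) * pop)
      rows[[idx]] <- data.frame(
        tract_id = sprintf("T%03d", idx),
        state = paste0("S", pmin(3, ceiling(3 * tcx / ntx))),
        area_km2 = tc^2,
        population_total = pop,
        white = round(jit(sh$white) * pop),
        non_hispanic = pop - h,
        hispanic = h,
        black = round(jit(sh$black) * pop),
        asian_nhpi = round(jit(sh$asian_nhpi) * pop),
        other = round(jit(sh$other) * pop),
        lon_min = b[1] + (tcx - 1) * tdeg, lon_max = b[1] + tcx * tdeg,
        lat_min = b[3] + (tr - 1) * tdeg, lat_max = b[3] + tr * tdeg,
        facility_count = 0L)
    }
  }
  tracts <- do.call(rbind, rows)
  if (!is.null(facilities)) {
    cnt <- table(factor(tract_index_of(config, facilities$lon, facilities$lat),
                        levels = seq_len(nrow(tracts))))
    tracts$facility_count <- as.integer(cnt)
  }

  set.seed(ww_sub_seed(config$seed, 2L))
  segs <- list()
  add_seg <- function(x0, y0, x1, y1, dmid) {
    total <- (4000 + 8 * dmid) * exp(rnorm(1, 0, 0.35))
    truck <- total * runif(1, 0.05, 0.12)
    len <- sqrt(((x1 - x0) / config$grid_step)^2 +
                  ((y1 - y0) / config$grid_step)^2)  # cells == km nominally
    data.frame(id = sprintf("road_%04d", length(segs) + 1),
               lon0 = x0, lat0 = y0, lon1 = x1, lat1 = y1,
               length_km = len, aadt_total = total, aadt_truck = truck,
               state = paste0("S", pmin(3, ceiling(3 * ((x0 + x1) / 2 - b[1]) /
                                                     (b[2] - b[1])))))
  }
  for (tr in seq_len(nty)) {
    clat <- b[3] + (tr - 0.5) * tdeg
    for (tcx in seq_len(ntx)) {
      x0 <- b[1] + (tcx - 1) * tdeg
      dmid <- ww_density_at(p, x0 + tdeg / 2, clat)
      segs[[length(segs) + 1]] <- add_seg(x0, clat, x0 + tdeg, clat, dmid)
    }
  }
  for (tcx in seq_len(ntx)) {
    clon <- b[1] + (tcx - 0.5) * tdeg
    for (tr in seq_len(nty)) {
      y0 <- b[3] + (tr - 1) * tdeg
      dmid <- ww_density_at(p, clon, y0 + tdeg / 2)
      segs[[length(segs) + 1]] <- add_seg(clon, y0, clon, y0 + tdeg, dmid)
    }
  }
  roads <- do.call(rbind, segs)

  if (!is.null(facilities)) {
    set.seed(ww_sub_seed(config$seed, 21L))
    n <- nrow(facilities)
    truck <- pmax(0, config$truck_base +
                    config$truck_slope_per_dock * facilities$docks_true +
                    config$truck_slope_per_cluster * (facilities$clustering - 1) +
                    config$truck_slope_per_parking * facilities$parking_true +
                    rnorm(n, 0, config$truck_noise_sd))
    total <- truck + 1500 * exp(rnorm(n, 0, 0.3))
    # keep the access segment inside the domain near the east edge
    x1 <- pmin(facilities$lon + config$grid_step, b[2] - 1e-9)
    acc <- data.frame(id = paste0("acc_", facilities$id),
                      lon0 = facilities$lon, lat0 = facilities$lat,
                      lon1 = x1, lat1 = facilities$lat,
                      length_km = 1,
                      aadt_total = total, aadt_truck = truck,
                      state = facilities$state)
    roads <- rbind(roads, acc)
  }
  list(roads = roads, tracts = tracts)
}

#' Generate facilities by a biased clustered point process
#'
#' Parent cluster centers are drawn across tracts with probability
#' proportional to tract population times `(siting subgroup share)
#' ^ siting_bias` (so `siting_bias = 0` gives population-weighted,
#' demographically unbiased siting); offspring facilities scatter around
#' their parent with `cluster_sd_km`. Characteristics (building area,
#' loading docks, parking spaces) are drawn positively correlated;
#' docks/parking are masked missing completely at random at the configured
#' rates (the `*_true` columns retain the generating values).
#'
#' @param config A [scenario_config()].
#' @param tracts Tract table from [generate_roads_and_tracts()]; must be
#'   non-empty.
#' @return List with `facilities` (data frame: id, lon, lat, tract_id,
#'   state, building_area_sqft, year_built, docks_true/parking_true,
#'   docks/parking with missingness, clustering) and `truth` (per-facility
#'   plume amplitude, local background, and true enhancement percent).
#' @export
generate_facilities <- function(config, tracts) {
  if (is.null(tracts) || nrow(tracts) == 0) stop("tracts must be non-empty")
  if (config$n_facilities < 1) stop("zero facilities requested")
  p <- ww_surface_params(config)
  b <- config$domain_bounds
  set.seed(ww_sub_seed(config$seed, 3L))
  share <- tracts[[config$siting_subgroup]] / pmax(tracts$population_total, 1)
  wts <- pmax(tracts$population_total, 1) * (share + 0.01)^config$siting_bias
  prob <- wts / sum(wts)
  sd_deg <- config$cluster_sd_km * config$grid_step
  n <- config$n_facilities
  lon <- numeric(0); lat <- numeric(0)
  guard <- 0
  while (length(lon) < n) {
    guard <- guard + 1
    if (guard > 50 * n) stop("facility placement failed to converge")
    ti <- sample.int(nrow(tracts), 1, prob = prob)
    px <- runif(1, tracts$lon_min[ti], tracts$lon_max[ti])
    py <- runif(1, tracts$lat_min[ti], tracts$lat_max[ti])
    n_off <- 1 + rpois(1, max(0, config$cluster_intensity - 1))
    for (j in seq_len(n_off)) {
      if (length(lon) >= n) break
      for (try in 1:20) {   # out-of-domain offspring are rejected and resampled
        ox <- px + rnorm(1, 0, sd_deg)
        oy <- py + rnorm(1, 0, sd_deg)
        if (ox > b[1] && ox < b[2] && oy > b[3] && oy < b[4]) {
          lon <- c(lon, ox); lat <- c(lat, oy)
          break
        }
      }
    }
  }
  tid <- tract_index_of(config, lon, lat)
  clustering <- as.integer(table(factor(tid, levels = seq_len(nrow(tracts))))[tid])
  # correlated characteristics via a latent Gaussian with 0.6 cross-correlation
  S <- matrix(0.6, 3, 3); diag(S) <- 1
  z <- matrix(rnorm(3 * n), n, 3) %*% chol(S)
  docks_true <- pmax(1, round(exp(1.7 + 0.55 * z[, 1])))
  parking_true <- pmax(0, round(exp(4.0 + 0.7 * z[, 2])))
  area <- round(20000 * exp(0.4 + 0.9 * z[, 3]))
  docks <- docks_true
  docks[runif(n) < config$missing_docks_frac] <- NA
  parking <- parking_true
  parking[runif(n) < config$missing_parking_frac] <- NA
  fac <- data.frame(
    id = sprintf("F%04d", seq_len(n)),
    lon = lon, lat = lat,
    tract_id = tracts$tract_id[tid],
    state = tracts$state[tid],
    building_area_sqft = area,
    year_built = sample(1970:2021, n, replace = TRUE),
    docks_true = docks_true, parking_true = parking_true,
    docks = docks, parking = parking,
    clustering = clustering)
  A <- config$plume_amplitude_per_dock * docks_true +
    config$plume_amplitude_per_cluster * (clustering - 1)
  g <- grid_from_config(config)
  dens <- ww_density_matrix(config)
  cells <- mapply(function(lo, la) unlist(nearest_cell(g, lo, la)), lon, lat)
  B <- config$background_base +
    config$background_density_coeff * dens[cbind(cells[1, ], cells[2, ])]
  truth <- data.frame(id = fac$id, amplitude = A, background = B,
                      enhancement_pct = 100 * A / B)
  list(facilities = fac, truth = truth)
}

#' Generate hourly coarse-grid wind fields
#'
#' Zonal/meridional components on a 0.25 degree grid, hourly for each day:
#' AR(1) day-to-day means, AR(1) hour-to-hour deviations, plus a small
#' random spatial gradient per day, so the fields vary smoothly in time and
#' space. `constant_wind` forces every hourly field to a constant vector.
#'
#' @param config A [scenario_config()].
#' @return Object of class `ww_winds`: `spec` (coarse grid), arrays `u`,
#'   `v` of dim `n_lat x n_lon x 24 x n_days`, `hours = 0:23`, `n_days`.
#' @export
generate_wind_fields <- function(config) {
  stopifnot(config$n_days >= 1)
  cg <- coarse_grid_from_config(config)
  nd <- config$n_days
  dm <- c(cg$n_lat, cg$n_lon, 24, nd)
  if (!is.null(config$constant_wind)) {
    return(structure(list(spec = cg,
                          u = array(config$constant_wind[1], dm),
                          v = array(config$constant_wind[2], dm),
                          hours = 0:23, n_days = nd), class = "ww_winds"))
  }
  set.seed(ww_sub_seed(config$seed, 4L))
  ar1 <- function(n, mu, sd, rho) {
    x <- numeric(n)
    x[1] <- rnorm(1, 0, sd)
    if (n > 1) for (i in 2:n) {
      x[i] <- rho * x[i - 1] + rnorm(1, 0, sd * sqrt(1 - rho^2))
    }
    mu + x
  }
  ud <- ar1(nd, config$wind_u_mean, config$wind_day_sd, config$wind_day_rho)
  vd <- ar1(nd, config$wind_v_mean, config$wind_day_sd, config$wind_day_rho)
  lons <- lon_centers(cg); lats <- lat_centers(cg)
  mlon <- mean(lons); mlat <- mean(lats)
  GX <- outer(rep(1, cg$n_lat), lons - mlon)
  GY <- outer(lats - mlat, rep(1, cg$n_lon))
  u <- array(0, dm); v <- array(0, dm)
  for (d in seq_len(nd)) {
    uh <- ar1(24, ud[d], config$wind_hour_sd, config$wind_hour_rho)
    vh <- ar1(24, vd[d], config$wind_hour_sd, config$wind_hour_rho)
    gxu <- rnorm(1, 0, 0.3); gyu <- rnorm(1, 0, 0.3)
    gxv <- rnorm(1, 0, 0.3); gyv <- rnorm(1, 0, 0.3)
    for (h in 1:24) {
      u[, , h, d] <- uh[h] + gxu * GX + gyu * GY
      v[, , h, d] <- vh[h] + gxv * GX + gyv * GY
    }
  }
  structure(list(spec = cg, u = u, v = v, hours = 0:23, n_days = nd),
            class = "ww_winds")
}

#' Generate daily NO2 column fields
#'
#' Each daily field is background (base plus density term, from the same
#' smooth density surface that generated tract populations) plus one
#' isotropic 2-D Gaussian bump per facility whose amplitude grows with
#' loading docks and clustering, centered `plume_displacement_km` downwind
#' along that day's overpass-window (16-20 UTC) mean wind at the facility;
#' multiplicative mean-one lognormal noise (cv = `noise_cv`) and a random
#' `swath_missing_frac` of masked cells emulate retrieval noise and swath
#' gaps.
#'
#' @param facilities Facility table from [generate_facilities()].
#' @param winds A `ww_winds` object overlapping the domain and days.
#' @param config A [scenario_config()].
#' @param hours Overpass hours passed to [prevailing_direction()].
#' @return List of daily [raster_field()]s (length `n_days`).
#' @export
generate_no2_fields <- function(facilities, winds, config, hours = 16:20) {
  g <- grid_from_config(config)
  b <- config$domain_bounds
  out_dom <- facilities$lon <= b[1] | facilities$lon >= b[2] |
    facilities$lat <= b[3] | facilities$lat >= b[4]
  if (any(out_dom)) {
    stop("facility outside raster domain: ",
         paste(facilities$id[out_dom], collapse = ", "))
  }
  dens <- ww_density_matrix(config)
  bg <- config$background_base + config$background_density_coeff * dens
  A <- config$plume_amplitude_per_dock * facilities$docks_true +
    config$plume_amplitude_per_cluster * (facilities$clustering - 1)
  sig <- config$plume_sigma_km          # cells == km nominally
  disp <- config$plume_displacement_km
  reach <- ceiling(4 * sig)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  n_mask <- round(config$swath_missing_frac * g$n_lat * g$n_lon)

  # facility positions in continuous cell units from the SW corner
  fx <- (facilities$lon - g$lon_origin) / g$step
  fy <- (facilities$lat - g$lat_origin) / g$step

  # prevailing winds drawn before seeding the noise stream
  dirs <- matrix(NA_real_, nrow(facilities), config$n_days)
  spd <- matrix(NA_real_, nrow(facilities), config$n_days)
  for (i in seq_len(nrow(facilities))) {
    for (d in seq_len(config$n_days)) {
      pw <- prevailing_direction(winds, facilities$lon[i], facilities$lat[i],
                                 d, hours = hours)
      dirs[i, d] <- if (pw$calm) NA_real_ else pw$direction_deg
      spd[i, d] <- pw$speed
    }
  }

  set.seed(ww_sub_seed(config$seed, 5L))
  fields <- vector("list", config$n_days)
  for (d in seq_len(config$n_days)) {
    f <- bg
    for (i in seq_len(nrow(facilities))) {
      th <- dirs[i, d]
      if (is.na(th)) { ux <- 0; uy <- 0 }                 # calm: no displacement
      else { ux <- cos(th * pi / 180); uy <- sin(th * pi / 180) }
      cx <- fx[i] + disp * ux
      cy <- fy[i] + disp * uy
      cols <- max(1, floor(cx - reach)):min(g$n_lon, ceiling(cx + reach) + 1)
      rws <- max(1, floor(cy - reach)):min(g$n_lat, ceiling(cy + reach) + 1)
      dxs <- (cols - 0.5) - cx
      dys <- (rws - 0.5) - cy
      bump <- A[i] * outer(exp(-dys^2 / (2 * sig^2)), exp(-dxs^2 / (2 * sig^2)))
      f[rws, cols] <- f[rws, cols] + bump
    }
    if (config$noise_cv > 0) {
      f <- f * matrix(exp(rnorm(length(f), -sdlog^2 / 2, sdlog)),
                      nrow(f), ncol(f))
    }
    if (n_mask > 0) {
      f[sample.int(length(f), n_mask)] <- NA_real_
    }
    fields[[d]] <- raster_field(g, f)
  }
  fields
}

#' Simulate coarse satellite footprints from a fine field
#'
#' Tiles the field into rectangular footprints of `fp_cells_lon x
#' fp_cells_lat` cells (about the 5 km x 3.5 km native retrieval footprint
#' on a 1 km grid), each carrying the mean of its underlying valid cells
#' and a QA value; a random `low_qa_frac` of footprints get QA 0.4 (below
#' the 0.75 operational cut).
#'
#' @param field A [raster_field()].
#' @param fp_cells_lon,fp_cells_lat Footprint size in cells.
#' @param low_qa_frac Fraction of low-quality footprints.
#' @param seed Optional integer seed.
#' @return Footprint data frame for [oversample()].
#' @export
footprints_from_field <- function(field, fp_cells_lon = 5, fp_cells_lat = 3,
                                  low_qa_frac = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- field$spec
  rows <- list()
  for (r0 in seq(1, g$n_lat, by = fp_cells_lat)) {
    for (c0 in seq(1, g$n_lon, by = fp_cells_lon)) {
      r1 <- min(g$n_lat, r0 + fp_cells_lat - 1)
      c1 <- min(g$n_lon, c0 + fp_cells_lon - 1)
      v <- mean(field$values[r0:r1, c0:c1], na.rm = TRUE)
      if (!is.finite(v)) next
      x0 <- g$lon_origin + (c0 - 1) * g$step
      x1 <- g$lon_origin + c1 * g$step
      y0 <- g$lat_origin + (r0 - 1) * g$step
      y1 <- g$lat_origin + r1 * g$step
      rows[[length(rows) + 1]] <- data.frame(
        lon1 = x0, lat1 = y0, lon2 = x1, lat2 = y0,
        lon3 = x1, lat3 = y1, lon4 = x0, lat4 = y1,
        value = v, qa = if (runif(1) < low_qa_frac) 0.4 else 0.95)
    }
  }
  do.call(rbind, rows)
}

#' Generate sectoral surface-emission rasters
#'
#' Eight nonnegative sector rasters (dust, non-point, oil and gas, rail,
#' residential wood combustion, on-road, non-road, airports); agricultural
#' ammonia is deliberately absent because it carries no NOx. The on-road
#' raster is proportional to the total-VKT raster, and the `total` raster
#' equals the sum of the sector rasters by construction.
#'
#' @param config A [scenario_config()].
#' @param roads Road-segment table.
#' @param facilities Facility table (unused by the default layers but part
#'   of the generator surface for sector variants).
#' @return List with `sectors` (named list of [raster_field()]s) and
#'   `total` (their sum).
#' @export
generate_emission_layers <- function(config, roads, facilities = NULL) {
  set.seed(ww_sub_seed(config$seed, 6L))
  g <- grid_from_config(config)
  dens <- ww_density_matrix(config)
  vkt <- rasterize_vkt(roads, g)$total$values
  lons <- lon_centers(g); lats <- lat_centers(g)
  b <- config$domain_bounds
  nx <- (lons - b[1]) / (b[2] - b[1])
  ny <- (lats - b[3]) / (b[4] - b[3])
  smooth_field <- function() {
    f <- matrix(0, g$n_lat, g$n_lon)
    for (k in 1:3) {
      kx <- runif(1, 0.5, 2.5); ky <- runif(1, 0.5, 2.5)
      ph <- runif(1, 0, 2 * pi)
      f <- f + runif(1, 0.3, 1) *
        outer(cos(2 * pi * ky * ny), cos(2 * pi * kx * nx + ph))
    }
    pmax(f + 1.2, 0)
  }
  blobs <- function(n_blob, amp, sg) {
    f <- matrix(0, g$n_lat, g$n_lon)
    for (k in seq_len(n_blob)) {
      cx <- runif(1, 1, g$n_lon); cy <- runif(1, 1, g$n_lat)
      f <- f + amp * outer(exp(-((seq_len(g$n_lat) - cy)^2) / (2 * sg^2)),
                           exp(-((seq_len(g$n_lon) - cx)^2) / (2 * sg^2)))
    }
    f
  }
  airports <- matrix(0, g$n_lat, g$n_lon)
  airports[cbind(sample.int(g$n_lat, 2), sample.int(g$n_lon, 2))] <- 50
  sectors <- list(
    dust = 0.4 * smooth_field(),
    non_point = 0.3 * smooth_field() + 1e-4 * dens,
    oil_gas = blobs(3, 3, 6),
    rail = blobs(1, 2, 3) + 2 * exp(-((row(dens) - round(g$n_lat / 3))^2) / 8),
    residential_wood = 2e-4 * dens * smooth_field(),
    on_road = 1e-3 * vkt,
    non_road = 0.2 * smooth_field(),
    airports = airports)
  total <- Reduce(`+`, sectors)
  list(sectors = lapply(sectors, function(m) raster_field(g, m)),
       total = raster_field(g, total))
}

#' Generate a complete seeded scenario with ground truth
#'
#' Orchestrates tracts/roads, facilities (then roads again with the
#' facility access segments; the tract stream reproduces identically),
#' winds, daily NO2 fields, and emissions, and assembles the recorded
#' truth: per-facility plume amplitude/background/enhancement, the
#' composite-level enhancement `100 * mean(amplitude) / mean(background)`,
#' the planted displacement, the favored siting subgroup, and the planted
#' truck-VKT slopes (structural, plus the univariate slope implied by the
#' correlated characteristics — the target an unconditional simple
#' regression recovers).
#'
#' @param config A [scenario_config()].
#' @return Object of class `ww_scenario`: `config`, `tracts`, `roads`,
#'   `facilities`, `winds`, `no2` (list of daily rasters), `emissions`,
#'   `truth`.
#' @export
generate_scenario <- function(config) {
  rt0 <- generate_roads_and_tracts(config)
  gf <- generate_facilities(config, rt0$tracts)
  rt <- generate_roads_and_tracts(config, gf$facilities)
  winds <- generate_wind_fields(config)
  no2 <- generate_no2_fields(gf$facilities, winds, config)
  emis <- generate_emission_layers(config, rt$roads, gf$facilities)
  fac <- gf$facilities
  slopes <- local({
    s <- c(dock = config$truck_slope_per_dock,
           cluster = config$truck_slope_per_cluster,
           parking = config$truck_slope_per_parking)
    chars <- cbind(dock = fac$docks_true, cluster = fac$clustering,
                   parking = fac$parking_true)
    cv <- stats::cov(chars)
    uni <- vapply(colnames(chars), function(ch)
      sum(s * cv[, ch]) / cv[ch, ch], numeric(1))
    data.frame(characteristic = colnames(chars), structural = as.numeric(s),
               univariate = as.numeric(uni))
  })
  # Composite-level truth: the enhancement statistic evaluated on the
  # noise-free, unmasked fields. Unlike the per-facility analytic value
  # (isolated plume over local background), this includes the overlap of
  # clustered neighbours' plumes, which the composite genuinely contains;
  # the recovery gap it leaves for tests is then purely retrieval noise
  # and swath masking.
  nf_truth <- local({
    no2_0 <- if (config$noise_cv == 0 && config$swath_missing_frac == 0) {
      no2
    } else {
      cfg0 <- config
      cfg0$noise_cv <- 0
      cfg0$swath_missing_frac <- 0
      generate_no2_fields(fac, winds, cfg0)
    }
    fw <- facility_rotated_windows(no2_0, winds, fac)
    enhancement(composite(lapply(fw, composite)))
  })
  truth <- list(
    per_facility = gf$truth,
    composite_enhancement_pct = nf_truth$enhancement_pct,
    analytic_enhancement_pct = 100 * mean(gf$truth$amplitude) /
      mean(gf$truth$background),
    composite_displacement_km = nf_truth$displacement_km,
    displacement_km = config$plume_displacement_km,
    favored_subgroup = config$siting_subgroup,
    siting_bias = config$siting_bias,
    slopes = slopes)
  structure(list(config = config, tracts = rt$tracts, roads = rt$roads,
                 facilities = fac, winds = winds, no2 = no2,
                 emissions = emis, truth = truth),
            class = "ww_scenario")
}

#' @export
print.ww_scenario <- function(x, ...) {
  cat(sprintf("<ww_scenario> %d facilities, %d tracts, %d days, seed %d\n",
              nrow(x$facilities), nrow(x$tracts), x$config$n_days,
              x$config$seed))
  invisible(x)
}
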