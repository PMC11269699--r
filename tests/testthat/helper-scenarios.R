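# Shared fixture builders; everything is generated in code at test time.

small_config <- function(seed = 1, n_facilities = 30, n_days = 4, ...) {
  scenario_config(domain_bounds = c(-100, -99.1, 36, 36.9),
                  n_facilities = n_facilities, n_days = n_days,
                  seed = seed, ...)
}

# quiet scenario: no retrieval noise, no swath gaps
noise_free_config <- function(seed = 1, ...) {
  small_config(seed = seed, noise_cv = 0, swath_missing_frac = 0, ...)
}

make_grid <- function(n = 20, step = 0.01, lon0 = -100, lat0 = 36) {
  grid_spec(lon0, lat0, step, n, n)
}

const_field <- function(grid, v) {
  raster_field(grid, matrix(v, grid$n_lat, grid$n_lon))
}

# square buffer window with a point plume at an (east, north) cell offset
plume_buffer <- function(radius = 10, east = 0, north = 0,
                         background = 0, amplitude = 1) {
  n <- 2 * radius + 1
  m <- matrix(background, n, n)
  m[radius + 1 + north, radius + 1 + east] <- background + amplitude
  m
}

# axis-aligned rectangular footprint row for oversample()
rect_footprint <- function(x0, x1, y0, y1, value, qa = 0.9) {
  data.frame(lon1 = x0, lat1 = y0, lon2 = x1, lat2 = y0,
             lon3 = x1, lat3 = y1, lon4 = x0, lat4 = y1,
             value = value, qa = qa)
}
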