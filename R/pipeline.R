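# End-to-end orchestration: simulate -> rotate/composite -> enhancement ->
# traffic -> equity -> report, with seed control and a reproducible
# manifest. The stages are plain functions so each is runnable standalone
# on prior outputs.

#' Rotated daily near-facility windows
#'
#' For every facility and day: computes the prevailing overpass wind,
#' extracts a buffered window from the daily field (radius
#' `ceiling(radius * sqrt(2))` so rotated corners stay covered) and rotates
#' it into the wind frame. Calm days (undefined direction) are dropped;
#' their count is recorded in attribute `n_calm`.
#'
#' @param no2 List of daily [raster_field()]s.
#' @param winds A `ww_winds` object.
#' @param facilities Facility data frame with `id`, `lon`, `lat`.
#' @param radius Output window radius in cells (default 7).
#' @param hours Overpass hours (default 16:20 UTC).
#' @param speed_floor Calm threshold (m/s).
#' @param method Rotation interpolation, `"bilinear"` or `"nearest"`.
#' @return List (per facility) of lists of rotated windows.
#' @export
facility_rotated_windows <- function(no2, winds, facilities, radius = 7,
                                     hours = 16:20, speed_floor = 0,
                                     method = "bilinear") {
  buf_r <- ceiling(radius * sqrt(2))
  n_calm <- 0L
  out <- lapply(seq_len(nrow(facilities)), function(i) {
    ws <- list()
    for (d in seq_along(no2)) {
      pw <- prevailing_direction(winds, facilities$lon[i], facilities$lat[i],
                                 d, hours = hours, speed_floor = speed_floor)
      if (pw$calm) { n_calm <<- n_calm + 1L; next }
      buf <- extract_window(no2[[d]], facilities$lon[i], facilities$lat[i],
                            buf_r)
      ws[[length(ws) + 1]] <- rotate_window(buf, pw$direction_deg, radius,
                                            method = method)
    }
    ws
  })
  attr(out, "n_calm") <- n_calm
  out
}

#' Mean field over a list of daily rasters
#'
#' Per-cell mean over valid (unmasked) days; cells with no valid day are
#' masked.
#'
#' @param no2 List of daily [raster_field()]s on a common grid.
#' @return A [raster_field()].
#' @export
annual_mean_field <- function(no2) {
  stopifnot(length(no2) > 0)
  arr <- array(unlist(lapply(no2, `[[`, "values"), use.names = FALSE),
               dim = c(nrow(no2[[1]]$values), ncol(no2[[1]]$values),
                       length(no2)))
  cnt <- rowSums(!is.na(arr), dims = 2)
  mn <- rowSums(arr, na.rm = TRUE, dims = 2) / ifelse(cnt > 0, cnt, NA)
  raster_field(no2[[1]]$spec, matrix(mn, dim(arr)[1], dim(arr)[2]))
}

#' Per-facility spatially averaged NO2
#'
#' Mean of the valid cells in each facility's near-facility window of a
#' (typically annual-mean) field — the per-facility value entering the
#' population-weighted exposure.
#'
#' @param field A [raster_field()].
#' @param facilities Facility data frame.
#' @param radius Window radius in cells (default 7).
#' @return Numeric vector, one value per facility.
#' @export
facility_no2_means <- function(field, facilities, radius = 7) {
  vapply(seq_len(nrow(facilities)), function(i) {
    w <- extract_window(field, facilities$lon[i], facilities$lat[i], radius)
    mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order on either a simulation configuration
#' (`sim`) or pre-built inputs (`inputs`, a `ww_scenario`-shaped list):
#' exactly one of the two must be supplied. Stages: scenario, wind-rotated
#' compositing with overall and stratified enhancements (by tract density
#' class and clustering decile), gridded VKT with reference-total scaling
#' and decile-binned characteristic regressions, demographic disparity and
#' population-weighted exposure (national, by state, leave-states-out),
#' and the missingness-bias correlation report. If `outdir` is given all
#' tables are written as CSV together with a JSON run manifest (config
#' hash, seed, versions, file checksums).
#'
#' @param sim A [scenario_config()], or `NULL`.
#' @param inputs A prepared `ww_scenario`, or `NULL`.
#' @param outdir Optional output directory.
#' @param radius Near-facility window radius in cells (default 7).
#' @param hours Overpass wind hours (default 16:20 UTC).
#' @param edge_cols Upwind-edge column set for [enhancement()] (default 1).
#' @param density_mode Passed to [density_class()].
#' @param n_boot Bootstrap resamples for decile summaries (default 300).
#' @param alpha Significance threshold (default 0.05).
#' @param cell_km Nominal cell size in km (default 1).
#' @param speed_floor Calm-day wind-speed floor in m/s (default 0).
#' @param leave_out_states States excluded in the leave-out exposure
#'   recomputation (default none).
#' @return Object of class `ww_bundle` with the scenario, composites,
#'   enhancement tables, traffic regressions, equity tables, missingness
#'   report, warnings, and (if written) output paths.
#' @export
run_pipeline <- function(sim = NULL, inputs = NULL, outdir = NULL,
                         radius = 7, hours = 16:20, edge_cols = 1,
                         density_mode = "fixed", n_boot = 300, alpha = 0.05,
                         cell_km = 1, speed_floor = 0,
                         leave_out_states = character()) {
  if (is.null(sim) == is.null(inputs)) {
    stop("supply exactly one of `sim` (a scenario_config) or `inputs` (a scenario)")
  }
  notes <- character(0)
  scen <- if (!is.null(inputs)) inputs else generate_scenario(sim)

  # --- stage: wind-rotated compositing -------------------------------------
  fw <- facility_rotated_windows(scen$no2, scen$winds, scen$facilities,
                                 radius = radius, hours = hours,
                                 speed_floor = speed_floor)
  if (attr(fw, "n_calm") > 0) {
    notes <- c(notes, sprintf("%d calm facility-days dropped", attr(fw, "n_calm")))
  }
  fac_comps <- lapply(fw, composite)
  overall_comp <- composite(fac_comps)
  overall_enh <- enhancement(overall_comp, edge_cols = edge_cols,
                             cell_km = cell_km)

  tr_idx <- match(scen$facilities$tract_id, scen$tracts$tract_id)
  dens_cls <- density_class(scen$tracts, mode = density_mode)[tr_idx]
  clust_dec <- paste0("D", decile_bins(scen$facilities$clustering))
  by_density <- stratified_enhancement(fac_comps, dens_cls,
                                       edge_cols = edge_cols, cell_km = cell_km)
  by_clust <- stratified_enhancement(fac_comps, clust_dec,
                                     edge_cols = edge_cols, cell_km = cell_km)
  enh_table <- function(strat) {
    do.call(rbind, lapply(names(strat), function(nm) {
      e <- strat[[nm]]$enhancement
      data.frame(stratum = nm, n_facilities = strat[[nm]]$n_facilities,
                 upwind_edge_mean = e$upwind_edge_mean,
                 peak_value = e$peak_value,
                 enhancement_pct = e$enhancement_pct,
                 peak_east = e$peak_offset[["east"]],
                 peak_north = e$peak_offset[["north"]],
                 displacement_km = e$displacement_km)
    }))
  }

  # --- stage: traffic -------------------------------------------------------
  grid <- scen$no2[[1]]$spec
  roads <- segment_vkt(scen$roads)
  ref <- tapply(roads$vkt_total, roads$state, sum)
  roads <- scale_to_reference(roads, as.list(ref))   # identity scaling by construction
  vkt <- rasterize_vkt(roads, grid)
  nt <- do.call(rbind, lapply(seq_len(nrow(scen$facilities)), function(i) {
    s <- near_facility_traffic(vkt, scen$facilities$lon[i],
                               scen$facilities$lat[i], radius)
    data.frame(id = scen$facilities$id[i], total_vkt = s$total_vkt,
               truck_vkt = s$truck_vkt)
  }))
  fac_reg <- scen$facilities
  slopes <- rbind(
    decile_bin_regression(fac_reg, nt, "docks", alpha = alpha),
    decile_bin_regression(fac_reg, nt, "parking", scale = 10, alpha = alpha),
    decile_bin_regression(fac_reg, nt, "clustering", alpha = alpha))
  slope_summary <- do.call(rbind, lapply(split(slopes, slopes$characteristic),
    function(d) data.frame(characteristic = d$characteristic[1],
                           mean_slope = mean(d$slope, na.rm = TRUE),
                           n_bins = sum(!is.na(d$slope)),
                           n_significant = sum(d$significant, na.rm = TRUE))))

  # --- stage: equity --------------------------------------------------------
  ann <- annual_mean_field(scen$no2)
  fac_no2 <- facility_no2_means(ann, scen$facilities, radius)
  sub_cols <- c("population_total", ww_subgroups)
  fac_pops <- scen$tracts[tr_idx, sub_cols]
  disparity <- demographic_disparity(scen$tracts, alpha = alpha)
  pw <- pw_exposure_table(fac_no2, fac_pops)
  state_exp <- state_level_exposure(fac_no2, fac_pops, scen$facilities$state,
                                    leave_out = leave_out_states)

  # --- stage: missingness robustness check ---------------------------------
  dens_fac <- scen$tracts$population_total[tr_idx] / scen$tracts$area_km2[tr_idx]
  covs <- data.frame(no2 = fac_no2, density = dens_fac,
                     truck_vkt = nt$truck_vkt,
                     hispanic_share = tract_share(scen$tracts, "hispanic")[tr_idx],
                     black_share = tract_share(scen$tracts, "black")[tr_idx])
  missing_rep <- missingness_correlation(scen$facilities, covs)

  bundle <- structure(list(
    scenario = scen,
    composite = overall_comp,
    enhancement = overall_enh,
    enhancement_overall = enh_table(list(All = list(
      enhancement = overall_enh, n_facilities = nrow(scen$facilities)))),
    enhancement_by_density = enh_table(by_density),
    enhancement_by_clustering = enh_table(by_clust),
    near_traffic = nt,
    traffic_slopes = slopes,
    traffic_slope_summary = slope_summary,
    facility_no2 = fac_no2,
    disparity = disparity,
    pw_exposure = pw,
    state_exposure = state_exp,
    missingness = missing_rep,
    notes = notes,
    params = list(radius = radius, hours = hours, edge_cols = edge_cols,
                  density_mode = density_mode, alpha = alpha,
                  cell_km = cell_km, seed = scen$config$seed)
  ), class = "ww_bundle")

  if (!is.null(outdir)) {
    bundle$paths <- write_bundle(bundle, outdir)
  }
  bundle
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    enhancement_overall = bundle$enhancement_overall,
    enhancement_by_density = bundle$enhancement_by_density,
    enhancement_by_clustering = bundle$enhancement_by_clustering,
    traffic_slopes = as.data.frame(bundle$traffic_slopes),
    traffic_slope_summary = bundle$traffic_slope_summary,
    disparity = bundle$disparity,
    pw_exposure = bundle$pw_exposure,
    pw_by_state = bundle$state_exposure$by_state,
    missingness = bundle$missingness,
    near_traffic = bundle$near_traffic)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths[nm] <- p
  }
  cfg_json <- jsonlite::toJSON(unclass(bundle$scenario$config),
                               auto_unbox = TRUE, digits = NA, null = "null")
  cfg_path <- file.path(outdir, "config.json")
  writeLines(cfg_json, cfg_path)
  paths["config"] <- cfg_path
  manifest <- list(
    package_version = as.character(utils::packageVersion("warewind")),
    r_version = R.version.string,
    seed = bundle$params$seed,
    params = bundle$params[setdiff(names(bundle$params), "seed")],
    config_md5 = unname(tools::md5sum(cfg_path)),
    notes = bundle$notes,
    files = lapply(paths, function(p) unname(tools::md5sum(p))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(outdir, "manifest.json"))
  paths["manifest"] <- file.path(outdir, "manifest.json")
  paths
}

#' Human-readable summary of a pipeline run
#'
#' Renders the headline quantities of a result bundle — overall and
#' stratified enhancement, peak displacement, mean per-characteristic
#' truck-VKT slopes, siting disparities, and population-weighted relative
#' differences — as markdown text or a plain list carrying identical
#' numbers. Empty strata are flagged, never fabricated.
#'
#' @param bundle A `ww_bundle` from [run_pipeline()].
#' @param format `"markdown"` or `"list"`.
#' @return Character vector of markdown lines, or a named list.
#' @export
report <- function(bundle, format = c("markdown", "list")) {
  format <- match.arg(format)
  e <- bundle$enhancement
  ms <- bundle$traffic_slope_summary
  pw <- bundle$pw_exposure
  disp_any <- bundle$disparity[bundle$disparity$stratum == "Any", ]
  out <- list(
    n_facilities = nrow(bundle$scenario$facilities),
    n_days = length(bundle$scenario$no2),
    enhancement_pct = e$enhancement_pct,
    displacement_km = e$displacement_km,
    upwind_edge_mean = e$upwind_edge_mean,
    peak_value = e$peak_value,
    mean_slope = stats::setNames(ms$mean_slope, ms$characteristic),
    disparity_rel_diff_pct = stats::setNames(disp_any$relative_difference_pct,
                                             disp_any$subgroup),
    pw_rel_diff_pct = stats::setNames(pw$relative_difference_pct, pw$subgroup),
    notes = bundle$notes)
  if (format == "list") return(out)
  fmt <- function(x) formatC(x, digits = 4, format = "g")
  lines <- c(
    "# Near-facility NO2 analysis summary",
    "",
    sprintf("- Facilities: %d; days: %d", out$n_facilities, out$n_days),
    sprintf("- Composite NO2 enhancement: %s%% (upwind edge %s, peak %s)",
            fmt(out$enhancement_pct), fmt(out$upwind_edge_mean),
            fmt(out$peak_value)),
    sprintf("- Downwind peak displacement: %s km", fmt(out$displacement_km)),
    "",
    "## Truck-VKT slopes (mean across total-VKT decile bins)",
    sprintf("- per %s: %s km/day", names(out$mean_slope),
            fmt(out$mean_slope)),
    "",
    "## Siting disparities (tracts with facilities vs all tracts, median share)",
    sprintf("- %s: %s%%", names(out$disparity_rel_diff_pct),
            fmt(out$disparity_rel_diff_pct)),
    "",
    "## Population-weighted NO2 relative differences",
    sprintf("- %s: %s%%", names(out$pw_rel_diff_pct),
            fmt(out$pw_rel_diff_pct)))
  if (length(out$notes) > 0) {
    lines <- c(lines, "", "## Notes", paste0("- ", out$notes))
  }
  lines
}

#' @export
print.ww_bundle <- function(x, ...) {
  cat(sprintf("<ww_bundle> %d facilities; enhancement %.1f%%, displacement %.1f km\n",
              nrow(x$scenario$facilities), x$enhancement$enhancement_pct,
              x$enhancement$displacement_km))
  invisible(x)
}
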