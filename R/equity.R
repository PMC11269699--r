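# Demographic exposure analysis: population-density classes, siting
# disparities by clustering decile, population-weighted NO2 per subgroup,
# and state-level / leave-states-out variants.
#
# Tract tables carry one row per census tract with columns:
#   tract_id, state, area_km2, population_total, and the six non-mutually-
#   exclusive subgroup counts: white, non_hispanic, hispanic, black,
#   asian_nhpi (Asian, Native Hawaiian, or Pacific Islander), other (some
#   other race or two or more races), plus facility_count ("clustering").

ww_subgroups <- c("white", "non_hispanic", "hispanic", "black",
                  "asian_nhpi", "other")

#' Population-density class of tracts
#'
#' Density = total population / area. `mode = "fixed"` uses the national
#' tertile thresholds of 267 and 1501 people/km^2 (< 267 Low; 267-1501
#' Medium, boundaries assigned to Medium; > 1501 High). `mode = "tertile"`
#' recomputes tertile breakpoints from the supplied tracts.
#'
#' @param tracts Tract data frame with `population_total` and `area_km2`.
#' @param mode `"fixed"` (default) or `"tertile"`.
#' @return Factor with levels `Low`, `Medium`, `High`, one per tract.
#' @export
density_class <- function(tracts, mode = c("fixed", "tertile")) {
  mode <- match.arg(mode)
  stopifnot(all(tracts$area_km2 > 0))
  dens <- tracts$population_total / tracts$area_km2
  if (mode == "fixed") {
    lo <- 267; hi <- 1501
  } else {
    qs <- quantile(dens, c(1, 2) / 3, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  cls <- ifelse(dens < lo, "Low", ifelse(dens > hi, "High", "Medium"))
  factor(cls, levels = c("Low", "Medium", "High"))
}

tract_share <- function(tracts, subgroup) {
  stopifnot(subgroup %in% names(tracts))
  tracts[[subgroup]] / tracts$population_total
}

#' Demographic siting disparities by clustering stratum
#'
#' For the "Any" stratum (tracts containing at least one facility) and each
#' clustering decile (deciles of facility count among facility-containing
#' tracts, ties to the lower bin), compares each subgroup's tract-share
#' distribution against the all-tract (national) distribution: the relative
#' difference of medians, `100 * (median_stratum - median_all) /
#' median_all`, and a two-sample Kolmogorov-Smirnov test at `alpha`.
#'
#' @param tracts Tract data frame including `facility_count`.
#' @param subgroups Subgroup column names (default the six standard ones).
#' @param alpha Significance threshold (default 0.05).
#' @param low_n Strata with fewer tracts than this are flagged (default 5).
#' @return Data frame: `subgroup, stratum, n, median_share,
#'   national_median_share, relative_difference_pct, ks_stat, ks_p,
#'   significant, low_n`.
#' @export
demographic_disparity <- function(tracts, subgroups = ww_subgroups,
                                  alpha = 0.05, low_n = 5) {
  stopifnot("facility_count" %in% names(tracts))
  tracts <- tracts[tracts$population_total > 0, ]
  with_fac <- tracts$facility_count >= 1
  if (!any(with_fac)) stop("no tracts contain a facility")
  strata <- list(Any = which(with_fac))
  wf_idx <- which(with_fac)
  if (length(wf_idx) >= 10) {
    dec <- decile_bins(tracts$facility_count[wf_idx])
    for (b in sort(unique(dec))) {
      strata[[paste0("D", b)]] <- wf_idx[dec == b]
    }
  }
  rows <- list()
  for (sg in subgroups) {
    share_all <- tract_share(tracts, sg)
    med_all <- median(share_all)
    for (st in names(strata)) {
      idx <- strata[[st]]
      share_st <- share_all[idx]
      med_st <- median(share_st)
      rel <- if (med_all == 0) NA_real_ else 100 * (med_st - med_all) / med_all
      ks <- ks_two_sample(share_st, share_all)
      rows[[length(rows) + 1]] <- data.frame(
        subgroup = sg, stratum = st, n = length(idx),
        median_share = med_st, national_median_share = med_all,
        relative_difference_pct = rel,
        ks_stat = ks$statistic, ks_p = ks$p,
        significant = ks$p < alpha, low_n = length(idx) < low_n)
    }
  }
  do.call(rbind, rows)
}

#' Population-weighted near-facility NO2
#'
#' Computes `sum(NO2_i * pop_i) / sum(pop_i)` over facilities `i`, where
#' `NO2_i` is the spatially averaged NO2 in facility `i`'s near-facility
#' window and `pop_i` is the (total or subgroup) population of the tract
#' containing facility `i`. The result is a convex combination of the
#' facility values.
#'
#' @param no2 Numeric vector of per-facility spatially averaged NO2.
#' @param pop Nonnegative population weights, same length; must not sum
#'   to zero.
#' @return The population-weighted NO2 value.
#' @export
population_weighted_no2 <- function(no2, pop) {
  stopifnot(length(no2) == length(pop))
  ok <- is.finite(no2) & is.finite(pop)
  no2 <- no2[ok]; pop <- pop[ok]
  if (any(pop < 0)) stop("negative population weight")
  if (sum(pop) == 0) stop("total population weight is zero")
  sum(no2 * pop) / sum(pop)
}

#' Population-weighted exposure table across subgroups
#'
#' One row per subgroup: the population-weighted NO2 (Eq. of the
#' population-weighting convention above) and its percent difference from
#' the total-population-weighted value. No formal significance is attached:
#' these are comparisons between pairs of single values, not distributions.
#'
#' @param facility_no2 Per-facility spatially averaged NO2.
#' @param facility_pops Data frame (one row per facility) with
#'   `population_total` and the subgroup population columns of the
#'   facility's tract.
#' @param subgroups Subgroup column names.
#' @return Data frame `subgroup, no2_population_weighted,
#'   relative_difference_pct` (first row is `total`, identically 0).
#' @export
pw_exposure_table <- function(facility_no2, facility_pops,
                              subgroups = ww_subgroups) {
  ref <- population_weighted_no2(facility_no2, facility_pops$population_total)
  rows <- data.frame(subgroup = "total", no2_population_weighted = ref,
                     relative_difference_pct = 0)
  for (sg in subgroups) {
    v <- population_weighted_no2(facility_no2, facility_pops[[sg]])
    rows <- rbind(rows, data.frame(
      subgroup = sg, no2_population_weighted = v,
      relative_difference_pct = 100 * (v - ref) / ref))
  }
  rows
}

#' State-level exposure and leave-states-out recomputation
#'
#' Computes the per-state population-weighted relative differences (each
#' state's facilities only) and recomputes the national table after
#' excluding a named set of states. States with no facilities are omitted
#' with a warning; leaving out the empty set reproduces the national table.
#'
#' @param facility_no2 Per-facility spatially averaged NO2.
#' @param facility_pops Per-facility tract population data frame.
#' @param states Per-facility state code.
#' @param subgroups Subgroup column names.
#' @param leave_out Character vector of state codes to exclude from the
#'   national recomputation (default none).
#' @return List with `by_state` (data frame with a `state` column),
#'   `national` (on all facilities), `national_leave_out` (excluding
#'   `leave_out`), and `left_out`.
#' @export
state_level_exposure <- function(facility_no2, facility_pops, states,
                                 subgroups = ww_subgroups,
                                 leave_out = character()) {
  stopifnot(length(states) == length(facility_no2))
  by_state <- list()
  for (s in sort(unique(states))) {
    sel <- states == s
    if (!any(sel)) {
      warning(sprintf("state %s has no facilities; omitted", s))
      next
    }
    tb <- pw_exposure_table(facility_no2[sel],
                            facility_pops[sel, , drop = FALSE], subgroups)
    tb$state <- s
    by_state[[s]] <- tb
  }
  keep <- !(states %in% leave_out)
  if (!any(keep)) stop("leave_out excludes every facility")
  list(
    by_state = do.call(rbind, by_state),
    national = pw_exposure_table(facility_no2, facility_pops, subgroups),
    national_leave_out = pw_exposure_table(
      facility_no2[keep], facility_pops[keep, , drop = FALSE], subgroups),
    left_out = leave_out
  )
}
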