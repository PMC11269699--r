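# Self-contained statistical kernel shared by the analysis modules:
# Spearman rank correlation, OLS slope with a Wald t test, Mann-Kendall
# trend, two-sample Kolmogorov-Smirnov, decile summaries with bootstrap
# median CIs, and the missingness-bias correlation report.

#' Spearman rank correlation with a two-sided t approximation
#'
#' Average ranks are used for ties; the p-value comes from the two-sided t
#' approximation `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` (pairs with missing
#'   values are dropped).
#' @return List with `r`, `p`, `n`, and logical `degenerate` (`TRUE`, with
#'   missing `r`, when either vector has zero rank variance).
#' @export
spearman_rp <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) / ((n - 1) * sd(rx) * sd(ry))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n = n, degenerate = FALSE)
}

#' Simple least-squares slope with a Wald t test
#'
#' Fits `y = a + b x` by ordinary least squares and tests `b = 0` with a
#' two-sided Wald t test on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors (`n >= 3`; `var(x) > 0` required).
#' @return List with `slope`, `intercept`, `se`, `t`, `p`, `n` and
#'   `residuals`.
#' @export
ols_slope_wald <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("zero variance in x; slope undefined")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tt <- if (se == 0) sign(slope) * Inf else slope / se
  p <- if (is.infinite(tt)) 0 else 2 * pt(-abs(tt), df = n - 2)
  if (se == 0 && slope == 0) p <- 1
  list(slope = slope, intercept = intercept, se = se, t = tt, p = p,
       n = n, residuals = res)
}

#' Mann-Kendall trend test
#'
#' Computes the Mann-Kendall S statistic (sum of pairwise signs), its
#' tie-corrected variance, and a two-sided p-value from the normal
#' approximation with continuity correction. The relative change over the
#' period, `100 * (last - first) / first`, is also reported.
#'
#' @param series Numeric vector, `n >= 4`.
#' @return List of class `ww_trend`: `S`, `var_S`, `z`, `p`, `direction`
#'   (`"increasing"`, `"decreasing"`, `"none"`), `relative_change_pct`, `n`.
#' @export
mann_kendall <- function(series) {
  x <- series[is.finite(series)]
  n <- length(x)
  if (n < 4) stop("need at least 4 values")
  S <- 0
  for (i in seq_len(n - 1)) {
    S <- S + sum(sign(x[(i + 1):n] - x[i]))
  }
  S <- as.integer(round(S))
  tie_tab <- table(x)
  ties <- tie_tab[tie_tab > 1]
  var_S <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  if (var_S == 0) {
    z <- 0; p <- 1
  } else {
    z <- (S - sign(S)) / sqrt(var_S)
    p <- 2 * pnorm(-abs(z))
  }
  rel <- if (x[1] != 0) 100 * (x[n] - x[1]) / x[1] else NA_real_
  structure(list(S = S, var_S = var_S, z = z, p = p,
                 direction = if (p < 0.05 && S > 0) "increasing"
                             else if (p < 0.05 && S < 0) "decreasing"
                             else "none",
                 relative_change_pct = rel, n = n),
            class = "ww_trend")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the supremum of the absolute difference between the two
#' empirical CDFs. The default p-value is the asymptotic Kolmogorov series;
#' `exact = TRUE` uses the exact null distribution (delegated to
#' [stats::psmirnov()]; requires no ties).
#'
#' @param a,b Nonempty numeric samples.
#' @param exact Logical; exact p-value for small samples (default `FALSE`).
#' @return List with `statistic`, `p`, `n_a`, `n_b`, `method`.
#' @export
ks_two_sample <- function(a, b, exact = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) stop("both samples must be nonempty")
  pts <- sort(unique(c(a, b)))
  Fa <- findInterval(pts, sort(a)) / n
  Fb <- findInterval(pts, sort(b)) / m
  D <- max(abs(Fa - Fb))
  has_ties <- anyDuplicated(c(a, b)) > 0
  if (exact && !has_ties) {
    p <- 1 - psmirnov(D, sizes = c(n, m), two.sided = TRUE)
    method <- "exact"
  } else {
    ne <- n * m / (n + m)
    tval <- sqrt(ne) * D
    if (tval == 0) {
      p <- 1   # identical ECDFs; the Kolmogorov series is for tval > 0
    } else {
      k <- 1:100
      p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * tval^2))
      p <- min(1, max(0, p))
    }
    method <- "asymptotic"
  }
  list(statistic = D, p = p, n_a = n, n_b = m, method = method)
}

#' Decile bins of a numeric variable
#'
#' Rank-based bins: ties share the minimum rank and therefore fall in the
#' lower bin; when all values are distinct, bin sizes differ by at most 1,
#' and the bins partition the sample.
#'
#' @param x Numeric vector.
#' @param n_bins Number of quantile bins (default 10).
#' @return Integer vector of bin indices in `1..n_bins`.
#' @export
decile_bins <- function(x, n_bins = 10) {
  n <- length(x)
  stopifnot(n >= n_bins)
  r <- rank(x, ties.method = "min")
  as.integer(floor((r - 1) * n_bins / n) + 1L)
}

#' Per-decile medians with bootstrap confidence intervals
#'
#' Bins `values` by deciles of `by`, then reports the median and a 95
#' percent bootstrap percentile confidence interval per bin. Following the
#' convention that binning is for display only, the full-sample Spearman
#' correlation between `values` and `by` (unbinned) is attached as
#' attributes `spearman_r` / `spearman_p`.
#'
#' @param values Numeric response (e.g. near-facility NO2).
#' @param by Numeric binning variable (e.g. loading docks); `n >= 10`.
#' @param n_boot Bootstrap resamples (default 1000; fewer than 100 warns).
#' @param seed Optional integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return Data frame with `decile`, `n`, `median`, `ci_low`, `ci_high`.
#' @export
decile_summaries <- function(values, by, n_boot = 1000, seed = NULL,
                             conf = 0.95) {
  ok <- is.finite(values) & is.finite(by)
  values <- values[ok]; by <- by[ok]
  stopifnot(length(values) >= 10)
  if (n_boot < 100) warning("n_boot < 100; intervals will be unstable")
  if (!is.null(seed)) set.seed(seed)
  bins <- decile_bins(by)
  alpha <- (1 - conf) / 2
  rows <- lapply(sort(unique(bins)), function(b) {
    v <- values[bins == b]
    boots <- vapply(seq_len(n_boot), function(i)
      median(sample(v, length(v), replace = TRUE)), numeric(1))
    data.frame(decile = b, n = length(v), median = median(v),
               ci_low = unname(quantile(boots, alpha)),
               ci_high = unname(quantile(boots, 1 - alpha)))
  })
  out <- do.call(rbind, rows)
  sp <- spearman_rp(by, values)
  attr(out, "spearman_r") <- sp$r
  attr(out, "spearman_p") <- sp$p
  out
}

#' Correlation of missingness indicators with covariates
#'
#' For each characteristic with missing entries, computes the Spearman
#' correlation between the binary is-missing indicator and each covariate —
#' the robustness check that missing facility records are not concentrated
#' in high-pollution, high-traffic or minority areas.
#'
#' @param facilities Data frame containing the characteristic columns.
#' @param covariates Data frame (same rows) of numeric covariates, e.g.
#'   near-facility NO2, population density, subgroup shares, truck VKT.
#' @param characteristics Character names of `facilities` columns whose
#'   missingness is examined (default `c("docks", "parking")`).
#' @return Data frame `characteristic, covariate, r, p, n, note`; `r` is
#'   `NA` with an explanatory note when a characteristic is entirely
#'   missing or entirely observed.
#' @export
missingness_correlation <- function(facilities, covariates,
                                    characteristics = c("docks", "parking")) {
  stopifnot(nrow(facilities) == nrow(covariates))
  rows <- list()
  for (ch in characteristics) {
    flag <- as.numeric(is.na(facilities[[ch]]))
    for (cv in names(covariates)) {
      if (all(flag == 1) || all(flag == 0)) {
        rows[[length(rows) + 1]] <- data.frame(
          characteristic = ch, covariate = cv, r = NA_real_, p = NA_real_,
          n = length(flag),
          note = if (all(flag == 1)) "all missing" else "none missing")
        next
      }
      sp <- spearman_rp(flag, covariates[[cv]])
      rows[[length(rows) + 1]] <- data.frame(
        characteristic = ch, covariate = cv, r = sp$r, p = sp$p, n = sp$n,
        note = "")
    }
  }
  do.call(rbind, rows)
}
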