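test_that("Spearman correlation matches brute-force ranks and cor.test", {
  expect_equal(spearman_rp(1:10, (1:10)^2)$r, 1)
  expect_equal(spearman_rp(1:10, -(1:10))$r, -1)
  expect_true(spearman_rp(rep(1, 5), 1:5)$degenerate)
  set.seed(101)
  for (i in 1:40) {
    n <- sample(5:20, 1)
    x <- sample(1:6, n, replace = TRUE)   # ties on purpose
    y <- sample(1:6, n, replace = TRUE) + rnorm(n, 0, 0.01)
    s <- spearman_rp(x, y)
    if (is.na(s$r)) next
    expect_equal(s$r, oracle_spearman_r(x, y), tolerance = 1e-10)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(s$r, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(s$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("OLS slope, SE and Wald p agree with lm and the closed form", {
  ex <- ols_slope_wald(1:20, 2 * (1:20) + 1)
  expect_equal(ex$slope, 2, tolerance = 1e-12)
  expect_lt(ex$p, 1e-12)
  expect_error(ols_slope_wald(rep(2, 5), rnorm(5)), "zero variance")
  set.seed(102)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- 1 + 0.5 * x + rnorm(n)
    f <- ols_slope_wald(x, y)
    # closed-form definition
    expect_equal(f$slope, sum((x - mean(x)) * (y - mean(y))) /
                   sum((x - mean(x))^2), tolerance = 1e-12)
    cf <- summary(lm(y ~ x))$coefficients
    expect_equal(f$slope, cf[2, 1], tolerance = 1e-10)
    expect_equal(f$se, cf[2, 2], tolerance = 1e-10)
    expect_equal(f$p, cf[2, 4], tolerance = 1e-10)
  }
})

test_that("Mann-Kendall S, tie-corrected variance and degenerate cases", {
  expect_equal(mann_kendall(1:10)$S, 45)
  cst <- mann_kendall(rep(3, 6))
  expect_equal(cst$S, 0)
  expect_equal(cst$p, 1)
  expect_equal(mann_kendall(c(1, 2, 3, 4))$relative_change_pct, 300)
  set.seed(103)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    x <- sample(1:4, n, replace = TRUE)
    expect_equal(mann_kendall(x)$S, oracle_mk_S(x))
  }
  # decreasing trend flagged
  expect_equal(mann_kendall(10:1)$direction, "decreasing")
})

test_that("two-sample KS statistic equals the ECDF sup-difference oracle", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)
  set.seed(104)
  for (i in 1:40) {
    a <- rnorm(sample(3:30, 1))
    b <- rnorm(sample(3:30, 1), 0.5)
    k <- ks_two_sample(a, b)
    expect_equal(k$statistic, oracle_ks_D(a, b), tolerance = 1e-12)
    ref <- suppressWarnings(ks.test(a, b))
    expect_equal(k$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
  # exact option for small untied samples
  set.seed(105)
  a <- rnorm(8); b <- rnorm(9)
  ke <- ks_two_sample(a, b, exact = TRUE)
  refe <- ks.test(a, b, exact = TRUE)
  expect_equal(ke$p, refe$p.value, tolerance = 1e-10)
})

test_that("decile bins partition the sample with ties in the lower bin", {
  x <- rnorm(100)
  b <- decile_bins(x)
  expect_equal(sort(unique(b)), 1:10)
  expect_true(all(table(b) == 10))
  # sizes differ by at most 1 for distinct values, any n
  b2 <- decile_bins(rnorm(103))
  expect_lte(diff(range(table(b2))), 1)
  # ties share the lower bin
  x3 <- c(rep(5, 30), 6:75)
  b3 <- decile_bins(x3)
  expect_equal(length(unique(b3[x3 == 5])), 1)
  expect_equal(unique(b3[x3 == 5]), 1L)
})

test_that("decile summaries: degenerate CIs, bin sizes, full-sample correlation", {
  d <- decile_summaries(rep(2, 50), 1:50, n_boot = 200, seed = 1)
  expect_true(all(d$median == 2 & d$ci_low == 2 & d$ci_high == 2))
  set.seed(106)
  v <- rnorm(100); by <- rnorm(100)
  d2 <- decile_summaries(v, by, n_boot = 200, seed = 2)
  expect_true(all(d2$n == 10))
  expect_true(all(d2$ci_low <= d2$median & d2$median <= d2$ci_high))
  expect_equal(attr(d2, "spearman_r"), spearman_rp(by, v)$r)
  expect_warning(decile_summaries(v, by, n_boot = 50, seed = 3), "n_boot")
})

test_that("bootstrap median CIs achieve near-nominal coverage", {
  set.seed(107)
  hits <- 0; n_sim <- 200
  for (i in 1:n_sim) {
    v <- rnorm(30)
    boots <- vapply(1:200, function(j)
      median(sample(v, 30, replace = TRUE)), numeric(1))
    ci <- quantile(boots, c(0.025, 0.975))
    if (ci[1] <= 0 && 0 <= ci[2]) hits <- hits + 1
  }
  expect_gt(hits / n_sim, 0.86)
  expect_lte(hits / n_sim, 1)
})

test_that("missingness correlations: MCAR near zero, systematic large", {
  set.seed(108)
  n <- 500
  fac <- data.frame(docks = 1:n, parking = 1:n)
  cov <- data.frame(z = rnorm(n))
  fac$docks[sample(n, 200)] <- NA                 # completely at random
  fac$parking[cov$z > median(cov$z)] <- NA        # driven by the covariate
  out <- missingness_correlation(fac, cov)
  r_mcar <- out$r[out$characteristic == "docks"]
  r_sys <- out$r[out$characteristic == "parking"]
  expect_lt(abs(r_mcar), 0.12)
  expect_gt(abs(r_sys), 0.8)
  # binary indicator vs its own driver: check against the rank oracle
  flag <- as.numeric(is.na(fac$parking))
  expect_equal(r_sys, oracle_spearman_r(flag, cov$z), tolerance = 1e-10)
  # degenerate flags are reported, not errors
  fac2 <- data.frame(docks = c(NA, NA), parking = c(1, 2))
  out2 <- missingness_correlation(fac2, data.frame(z = c(1, 2)))
  expect_equal(out2$note[out2$characteristic == "docks"], "all missing")
  expect_equal(out2$note[out2$characteristic == "parking"], "none missing")
})
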