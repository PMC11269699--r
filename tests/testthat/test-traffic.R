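seg <- function(x0, y0, x1, y1, total, truck, len = NULL, state = "S1",
                id = "r1") {
  if (is.null(len)) len <- sqrt((x1 - x0)^2 + (y1 - y0)^2) / 0.01
  data.frame(id = id, lon0 = x0, lat0 = y0, lon1 = x1, lat1 = y1,
             length_km = len, aadt_total = total, aadt_truck = truck,
             state = state)
}

test_that("segment VKT is AADT times length, additive under splitting", {
  s <- seg(0, 0, 0.02, 0, total = 1000, truck = 100, len = 2)
  v <- segment_vkt(s)
  expect_equal(v$vkt_total, 2000)
  expect_equal(v$vkt_truck, 200)
  expect_equal(segment_vkt(seg(0, 0, 0.01, 0, 500, 0, len = 1))$vkt_truck, 0)
  # splitting in half leaves the summed VKT unchanged
  halves <- rbind(seg(0, 0, 0.01, 0, 1000, 100, len = 1),
                  seg(0.01, 0, 0.02, 0, 1000, 100, len = 1))
  expect_equal(sum(segment_vkt(halves)$vkt_total), v$vkt_total)
  expect_error(segment_vkt(seg(0, 0, 0.01, 0, -5, 0, len = 1)), "negative AADT")
  expect_error(segment_vkt(seg(0, 0, 0.01, 0, 10, 20, len = 1)), "exceeds")
})

test_that("state scaling reproduces reference totals exactly and is idempotent", {
  s <- rbind(seg(0, 0, 0.01, 0, 1000, 100, len = 1, state = "A", id = "a"),
             seg(0, 0, 0.02, 0, 2000, 150, len = 2, state = "B", id = "b"))
  cur <- tapply(s$aadt_total * s$length_km, s$state, sum)
  # reference equal to current sums: identity
  same <- scale_to_reference(s, as.list(cur))
  expect_equal(same$aadt_total, s$aadt_total)
  expect_equal(same$aadt_truck, s$aadt_truck)
  # doubled reference doubles every AADT
  dbl <- scale_to_reference(s, as.list(cur * 2))
  expect_equal(dbl$aadt_total, s$aadt_total * 2)
  expect_equal(dbl$aadt_truck, s$aadt_truck * 2)
  # post-condition: per-state sums equal the reference to machine precision
  ref <- list(A = 3333.33, B = 777.77)
  sc <- scale_to_reference(s, ref)
  post <- tapply(sc$aadt_total * sc$length_km, sc$state, sum)
  expect_equal(unname(post["A"]), ref$A, tolerance = 1e-12)
  expect_equal(unname(post["B"]), ref$B, tolerance = 1e-12)
  expect_error(scale_to_reference(s, list(A = 1)), "no reference total")
})

test_that("VKT rasterization conserves totals and splits at cell boundaries", {
  g <- make_grid(10)
  # one short segment inside one cell carries its full VKT
  s1 <- seg(-99.985, 36.015, -99.981, 36.015, 1000, 100)
  r1 <- rasterize_vkt(s1, g)
  expect_equal(sum(r1$total$values), segment_vkt(s1)$vkt_total, tolerance = 1e-12)
  expect_equal(sum(r1$total$values > 0), 1)
  # a segment split evenly across two cells: half the VKT in each
  s2 <- seg(-99.995, 36.015, -99.985, 36.015, 1000, 100, len = 1)
  r2 <- rasterize_vkt(s2, g)
  on <- which(r2$total$values > 0)
  expect_equal(length(on), 2)
  expect_equal(r2$total$values[on], rep(500, 2), tolerance = 1e-9)
  # conservation over many random segments fully inside the grid
  set.seed(55)
  segs <- do.call(rbind, lapply(1:30, function(i) {
    x0 <- runif(1, -99.99, -99.93); y0 <- runif(1, 36.01, 36.07)
    seg(x0, y0, x0 + runif(1, 0, 0.02), y0 + runif(1, 0, 0.02),
        runif(1, 100, 5000), runif(1, 0, 100), id = paste0("s", i))
  }))
  rr <- rasterize_vkt(segs, g)
  v <- segment_vkt(segs)
  expect_lt(abs(sum(rr$total$values) / sum(v$vkt_total) - 1), 1e-9)
  expect_lt(abs(sum(rr$truck$values) / sum(v$vkt_truck) - 1), 1e-9)
  # a segment leaving the grid is clipped with a warning
  expect_warning(rasterize_vkt(seg(-99.995, 36.005, -98, 36.005, 100, 10), g),
                 "clipped")
})

test_that("near-facility traffic sums shrink with radius and handle empty rasters", {
  g <- make_grid(20)
  set.seed(56)
  segs <- do.call(rbind, lapply(1:10, function(i) {
    x0 <- runif(1, -99.99, -99.83); y0 <- runif(1, 36.01, 36.17)
    seg(x0, y0, x0 + 0.02, y0, runif(1, 100, 1000), runif(1, 10, 90),
        id = paste0("s", i))
  }))
  vk <- rasterize_vkt(segs, g)
  lon <- lon_centers(g)[10]; lat <- lat_centers(g)[10]
  s7 <- near_facility_traffic(vk, lon, lat, 7)
  s3 <- near_facility_traffic(vk, lon, lat, 3)
  s1 <- near_facility_traffic(vk, lon, lat, 1)
  expect_true(s7$total_vkt >= s3$total_vkt && s3$total_vkt >= s1$total_vkt)
  expect_true(s7$truck_vkt <= s7$total_vkt)
  empty <- rasterize_vkt(segs[0, ], g)
  expect_equal(near_facility_traffic(empty, lon, lat, 7)$total_vkt, 0)
})

test_that("decile-bin regression recovers an exact linear law and flags bad bins", {
  set.seed(57)
  n <- 120
  fac <- data.frame(id = sprintf("F%03d", 1:n), docks = sample(1:40, n, TRUE))
  nt <- data.frame(id = fac$id, total_vkt = runif(n, 1e4, 1e6),
                   truck_vkt = 100 * fac$docks)   # exact law inside every bin
  r <- decile_bin_regression(fac, nt, "docks")
  expect_equal(nrow(r), 10)
  expect_true(all(abs(r$slope - 100) < 1e-8))
  expect_true(all(r$p < 1e-10))
  expect_equal(attr(r, "mean_slope"), 100, tolerance = 1e-8)
  # parking scaled by 10: slope reads per 10 spaces
  fac$parking <- fac$docks * 10
  r10 <- decile_bin_regression(fac, nt, "parking", scale = 10)
  expect_true(all(abs(r10$slope - 100) < 1e-8))
  # missing characteristics are dropped from this regression only
  fac2 <- fac; fac2$docks[1:15] <- NA
  r2 <- decile_bin_regression(fac2, nt, "docks")
  expect_equal(sum(r2$n), n - 15)
  # zero-variance bin flagged, not an error
  fac3 <- fac; fac3$docks <- rep(7, n)
  r3 <- decile_bin_regression(fac3, nt, "docks")
  expect_true(all(r3$flagged))
  expect_true(all(is.na(r3$slope)))
  expect_error(decile_bin_regression(fac[1:5, ], nt[1:5, ], "docks"),
               "at least 10")
})
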