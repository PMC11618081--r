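grid10 <- make_grid(c(0, 10), c(0, 10), 1)   # 10 x 10 all-ocean grid

test_that("core thresholds use interpolated percentiles with >= tie handling", {
  g <- make_grid(c(0, 10), c(0, 10), 1)
  m <- make_test_map(g, matrix(as.numeric(1:100), 10))
  core <- core_threshold(m, q = 90)
  expect_equal(core$threshold, 90.1)           # linear-interpolation percentile
  expect_equal(sum(core$mask), 10)             # cells 91..100
  # uniform map: every cell is core under the >= convention
  u <- make_test_map(g, matrix(0.4, 10, 10))
  expect_true(all(core_threshold(u, 90)$mask))
  # continuous map: core fraction 10% within one cell
  set.seed(80)
  r <- make_test_map(g, matrix(runif(100), 10))
  expect_lte(abs(sum(core_threshold(r, 90)$mask) - 10), 1)
  # sensitivity percentiles behave monotonically
  ns <- vapply(c(50, 75, 90, 95), function(q)
    sum(core_threshold(r, q)$mask), 0L)
  expect_true(all(diff(ns) < 0))
  # baseline-threshold mode applies the reference map's cutoff
  m2 <- make_test_map(g, matrix(as.numeric(1:100) + 50, 10))
  cb <- core_threshold(m2, 90, mode = "baseline_threshold", baseline_map = m)
  expect_equal(cb$threshold, 90.1)
  expect_equal(sum(cb$mask), 60)               # values 91.. -> 141..150 etc.
})

test_that("area change counts spherical cell areas", {
  g <- make_grid(c(0, 2), c(-1, 1), 0.25)
  base_mask <- matrix(FALSE, 8, 8)
  base_mask[3:4, 3:4] <- TRUE
  cur <- structure(list(mask = base_mask, grid = g), class = "core_habitat")
  fut_mask <- base_mask
  fut_mask[5, 4] <- TRUE                       # one extra near-equatorial cell
  fut <- structure(list(mask = fut_mask, grid = g), class = "core_habitat")
  expect_equal(habitat_area_change(cur, cur), 0)
  expect_equal(habitat_area_change(cur, fut), 772.6, tolerance = 1e-3)
  none <- structure(list(mask = base_mask & FALSE, grid = g),
                    class = "core_habitat")
  expect_equal(habitat_area_change(cur, none), -core_area_km2(cur))
})

test_that("latitudinal shifts scale with 111.32 km per degree and divide by time", {
  g <- make_grid(c(0, 10), c(0, 10), 0.25)
  mk <- function(jrows) {
    m <- matrix(FALSE, 40, 40); m[10:20, jrows] <- TRUE
    structure(list(mask = m, grid = g), class = "core_habitat")
  }
  cur <- mk(10:20)
  expect_true(all(latitudinal_shift(cur, cur, 38.5)$shift_km == 0))
  # shift the whole mask one 0.25-degree row north
  fut <- mk(11:21)
  sh <- latitudinal_shift(cur, fut, 38.5)
  north <- sh[sh$edge == "north", ]
  expect_equal(north$shift_km, 0.25 * 111.32, tolerance = 1e-12)
  expect_equal(north$shift_km, 27.83, tolerance = 1e-9)
  expect_equal(north$rate_km_yr, 27.83 / 38.5, tolerance = 1e-9)
  # south edge moved north: negative southward shift
  expect_equal(sh$shift_km[sh$edge == "south"], -27.83, tolerance = 1e-9)

  # equivariance: translating both masks leaves shifts unchanged;
  # translating only the future mask changes the north edge by delta * 111.32
  cur2 <- mk(12:22); fut2 <- mk(13:23)
  expect_equal(latitudinal_shift(cur2, fut2, 38.5)$shift_km, sh$shift_km)
  fut3 <- mk(15:25)   # future-only translation by 4 extra rows
  sh3 <- latitudinal_shift(cur, fut3, 38.5)
  expect_equal(sh3$shift_km[sh3$edge == "north"] - north$shift_km,
               111.32, tolerance = 1e-9)
  expect_error(latitudinal_shift(cur, mk(integer(0)), 38.5), "empty")
  expect_equal(elapsed_years_for("2046-2055"), 38.5)
  expect_equal(elapsed_years_for("2086-2095"), 78.5)
})

test_that("change maps classify with strict half-unit thresholds", {
  g <- grid10
  cur <- make_test_map(g, matrix(0.2, 10, 10))
  same <- change_map(cur, cur)
  expect_true(all(same$class == "no_change"))
  fut_vals <- matrix(0.2, 10, 10)
  fut_vals[1, 1] <- 0.7    # delta exactly 0.5: strict, so no_change
  fut_vals[2, 1] <- 0.8    # delta 0.6: increase
  fut_vals[3, 1] <- 0.2 - 0.6  # decrease
  ch <- change_map(cur, make_test_map(g, fut_vals))
  expect_equal(ch$class[1, 1], "no_change")
  expect_equal(ch$class[2, 1], "increase")
  expect_equal(ch$class[3, 1], "decrease")
  expect_equal(ch$delta[2, 1], 0.6, tolerance = 1e-12)
})

test_that("zonal summaries average by area and measure core coverage", {
  g <- make_grid(c(0, 10), c(-5, 5), 0.5)
  regions <- data.frame(region_id = c("L", "R"), name = c("left", "right"),
                        lon_min = c(0, 5), lon_max = c(5, 10),
                        lat_min = -5, lat_max = 5)
  class(regions) <- c("region_set", "data.frame")
  u <- make_test_map(g, matrix(0.3, 20, 20))
  core_all <- core_threshold(u, 90)            # uniform: everything core
  z <- zonal_summary(u, core_all, regions, period = "x")
  expect_equal(z$mean_suitability, c(0.3, 0.3))
  expect_equal(z$core_coverage_pct, c(100, 100))

  # core only in the left region: left 100%, right 0%
  mask <- outer(g$lon < 5, rep(TRUE, 20))
  core_left <- structure(list(mask = mask, grid = g), class = "core_habitat")
  z2 <- zonal_summary(u, core_left, regions)
  expect_equal(z2$core_coverage_pct, c(100, 0))

  # half-split region at the equator: coverage 50% within a cell's worth
  whole <- data.frame(region_id = "W", name = "w", lon_min = 0, lon_max = 10,
                      lat_min = -5, lat_max = 5)
  class(whole) <- c("region_set", "data.frame")
  south <- structure(list(mask = outer(rep(TRUE, 20), g$lat < 0), grid = g),
                     class = "core_habitat")
  z3 <- zonal_summary(u, south, whole)
  expect_equal(z3$core_coverage_pct, 50, tolerance = 0.02)
})

test_that("monthly summaries are flat for static fields and average to the annual mean", {
  g <- grid10
  regions <- data.frame(region_id = "A", name = "a", lon_min = 0,
                        lon_max = 10, lat_min = 0, lat_max = 10)
  class(regions) <- c("region_set", "data.frame")
  flat <- lapply(1:12, function(m) make_test_map(g, matrix(0.25, 10, 10)))
  ms <- monthly_summary(flat, regions)
  expect_equal(ms$mean_suitability, rep(0.25, 13))
  # sinusoidal seasonal signal passes through with matching phase
  seas <- lapply(1:12, function(m)
    make_test_map(g, matrix(0.5 + 0.3 * sin(2 * pi * m / 12), 10, 10)))
  ms2 <- monthly_summary(seas, regions)
  monthly <- ms2$mean_suitability[!is.na(ms2$month)]
  expect_equal(which.max(monthly), 3)          # sin peaks at month 3
  ann <- ms2$mean_suitability[is.na(ms2$month)]
  expect_equal(ann, mean(monthly), tolerance = 1e-9)
  expect_error(monthly_summary(flat[1:11], regions), "12")
})
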