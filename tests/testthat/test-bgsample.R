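test_that("MCP is the convex hull, with shoelace-verified area", {
  sq <- compute_mcp(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(polygon_area(sq), 1)
  expect_error(compute_mcp(c(0, 1), c(0, 1)), "3 distinct")
  expect_error(compute_mcp(c(0, 1, 2), c(0, 1, 2)), "collinear")

  set.seed(4)
  x <- rnorm(40); y <- rnorm(40)
  h <- compute_mcp(x, y)
  expect_true(all(point_in_mcp(h, x * 0.999, y * 0.999)))
  # shoelace oracle, written independently here
  shoelace <- function(px, py) {
    n <- length(px)
    abs(sum(px * py[c(2:n, 1)] - px[c(2:n, 1)] * py)) / 2
  }
  open <- h[-nrow(h), ]
  expect_equal(polygon_area(h), shoelace(open[, 1], open[, 2]),
               tolerance = 1e-12)
})

test_that("background sampling respects counts, the MCP exclusion and the 40-degree crop", {
  w <- tiny_world()
  daily <- w$daily[1:5, ]
  mcp <- compute_mcp(w$daily$lon, w$daily$lat)
  sp <- sampling_spec(seed = 3)
  bg <- sample_background(daily, w$fields, mcp, sp)
  expect_equal(nrow(bg), 500)                      # 100 per presence day
  expect_false(any(point_in_mcp(mcp, bg$lon, bg$lat)))
  expect_lte(max(abs(bg$lat)), 40)
  # deterministic given the seed
  bg2 <- sample_background(daily, w$fields, mcp, sp)
  expect_identical(bg$lon, bg2$lon)
  # backgrounds inherit their presence day's date
  expect_equal(unique(bg$date[bg$presence_row == 2]), daily$date[2])
})

test_that("ratio subsampling keeps exactly 10 backgrounds per presence", {
  w <- tiny_world()
  daily <- w$daily[1:3, ]
  mcp <- compute_mcp(w$daily$lon, w$daily$lat)
  sp <- sampling_spec(seed = 12)
  bg <- sample_background(daily, w$fields, mcp, sp)
  sub <- subsample_ratio(bg, sp)
  expect_equal(nrow(sub), 30)
  expect_true(all(table(sub$presence_row) == 10))
  expect_identical(subsample_ratio(bg, sp)$lon, sub$lon)
  one <- bg[bg$presence_row == 1, ][1:9, ]
  expect_error(subsample_ratio(one, sp), "insufficient")
})

test_that("annotation reproduces constant fields, window means and temporal interpolation", {
  g <- make_grid(c(0, 10), c(0, 10), 0.25)
  f <- make_test_fields(g, vars = list(
    const = function(lon, lat, m) 10 + 0 * lon,
    ramp = function(lon, lat, m) lon,
    seasonal = function(lon, lat, m) 10 * (m - 1)),
    static = list(flat = function(lon, lat, m) 7 + 0 * lon))
  pts <- data.frame(lon = 5.125, lat = 5.125,    # a cell centre
                    date = as.Date("2010-06-16"), tag_type = "ARGOS")
  em <- error_model(n_randomizations = 50)
  # constant field -> 10 regardless of the error model
  expect_equal(annotate_env(pts, f, em)$const, 10, tolerance = 1e-12)
  # static variables skip temporal interpolation
  expect_equal(annotate_env(pts, f, em)$flat, 7, tolerance = 1e-12)
  # no error model, point at a cell centre -> the window mean (single cell)
  expect_equal(annotate_env(pts, f, NULL)$ramp, 5.125, tolerance = 1e-12)

  # temporal linear interpolation between mid-month stamps: value 0 at the
  # mid-January stamp (doy 15.5), 10 at mid-February (doy 31 + 14 = 45);
  # 27 Jan sits (27 - 15.5) / (45 - 15.5) of the way along
  pts2 <- data.frame(lon = 5.125, lat = 5.125,
                     date = as.Date("2010-01-27"), tag_type = "ARGOS")
  expect_equal(annotate_env(pts2, f, NULL)$seasonal,
               10 * (27 - 15.5) / (45 - 15.5), tolerance = 1e-9)
})

test_that("annotation variance grows with positional error on a gradient field", {
  g <- make_grid(c(0, 40), c(0, 40), 0.25)
  f <- make_test_fields(g, vars = list(ramp = function(lon, lat, m) lon))
  set.seed(5)
  pts <- data.frame(lon = runif(80, 10, 30), lat = runif(80, 10, 30),
                    date = as.Date("2010-06-16"), tag_type = "ARGOS")
  vr <- vapply(c(0.1, 0.5, 2), function(sg) {
    em <- error_model(sigma = list(ARGOS = c(lon = sg, lat = sg)),
                      n_randomizations = 40)
    a <- annotate_env(pts, f, em, seed = 2)$ramp
    mean((a - pts$lon)^2)
  }, 0)
  expect_true(all(diff(vr) > 0))
})

test_that("spiral-order window enumeration averages to the plain window mean", {
  g <- make_grid(c(0, 5), c(0, 5), 0.05)    # native grid finer than 0.25
  set.seed(6)
  vals <- matrix(rnorm(length(g$lon) * length(g$lat)), length(g$lon))
  for (rep in 1:10) {
    x <- runif(1, 1, 4); y <- runif(1, 1, 4)
    sp <- spiral_window_values(vals, g, x, y, 0.25)
    expect_gt(length(sp), 1)
    expect_equal(mean(sp),
                 pelagicshift:::window_mean(vals, g, x, y, 0.25),
                 tolerance = 1e-12)
    # spiral starts at the cell containing the point
    ci <- cell_index(g, x, y)
    expect_equal(sp[1], vals[ci$i, ci$j])
  }
})

test_that("winsorize/centre/scale yields unit moments, clips tails, and round-trips", {
  set.seed(10)
  tab <- data.frame(region = rep(c("A", "B"), each = 200),
                    x = c(rnorm(200, 5, 2), rnorm(200, -3, 0.5)),
                    y = rexp(400))
  ws <- winsorize_and_scale(tab, c("x", "y"))
  for (reg in c("A", "B")) for (cv in c("x", "y")) {
    v <- ws$table[[cv]][ws$table$region == reg]
    expect_equal(mean(v), 0, tolerance = 1e-9)
    expect_equal(sd(v), 1, tolerance = 1e-9)
  }
  # values beyond p99 are clipped before scaling
  s <- ws$scaling$A$x
  big <- apply_scaling(1e6, ws$scaling, "A", "x")
  expect_equal(big, (s$hi - s$mean) / s$sd, tolerance = 1e-12)
  # applying the stored record to raw training data reproduces the table
  again <- apply_scaling(tab$x[tab$region == "A"], ws$scaling, "A", "x")
  expect_equal(again, ws$table$x[ws$table$region == "A"], tolerance = 1e-12)
  # zero-variance covariate is rejected by name
  tab$z <- 1
  expect_error(winsorize_and_scale(tab, "z"), "z")
})

test_that("the final model table satisfies its invariants on multiple seeds", {
  w <- tiny_world()
  for (sd in c(2, 17)) {
    pb <- build_pb_table(w$daily[1:20, ], w$fields,
                         sampling_spec(seed = sd), error_model())
    n1 <- sum(pb$table$label == 1); n0 <- sum(pb$table$label == 0)
    expect_equal(n0, 10 * n1)
    expect_lte(max(abs(pb$table$lat[pb$table$label == 0])), 40)
    bgr <- pb$table[pb$table$label == 0, ]
    expect_false(any(point_in_mcp(pb$mcp, bgr$lon, bgr$lat)))
  }
})
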