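spec_small <- function(seed = 5)
  world_spec(lon_range = c(-20, 10), lat_range = c(-20, 20), seed = seed)

test_that("environmental fields are deterministic, analytic at zero noise, and positive where required", {
  s <- spec_small()
  f1 <- gen_env_fields(s)
  f2 <- gen_env_fields(s)
  expect_identical(f1$vars, f2$vars)

  f0 <- gen_env_fields(s, noise_sd = list(sst = 0, chl = 0, sal = 0))
  # zero-noise SST equals the closed form at every (lat, month)
  for (m in c(1, 7)) {
    ocean_row <- which(!f0$land[, 1])[1]
    expect_equal(f0$vars$sst[ocean_row, , m],
                 sst_closed_form(s$grid$lat, m, f0$meta$pars),
                 tolerance = 1e-12)
  }
  expect_gt(min(f1$vars$chl, na.rm = TRUE), 0)
  # land cells masked in all variables
  expect_true(all(is.na(f1$vars$sst[f1$land])))
  expect_true(all(is.na(f1$static$bathy[f1$land])))
})

test_that("track fixes carry the printed tag error radii", {
  expect_equal(pelagicshift:::tag_error_sigma("ARGOS"),
               c(lon = 0.12, lat = 0.12))
  expect_equal(pelagicshift:::tag_error_sigma("PSAT"),
               c(lon = 0.53, lat = 1.08))
  # observation error around the true path has roughly those sd's
  s <- spec_small(9)
  tr <- gen_tracks(s, truth_suitability(), n_animals = 25,
                   mean_duration = 60, psat_prob = 0, gap_fraction = 0)
  tp <- attr(tr, "truth_paths")
  tr$date <- as.Date(tr$timestamp, tz = "UTC")
  m <- merge(tr, tp, by = c("animal_id", "date"), suffixes = c("", ".true"))
  expect_equal(sd(m$lat - m$lat.true), 0.12, tolerance = 0.1)
  expect_equal(sd(m$lon - m$lon.true), 0.12, tolerance = 0.1)
})

test_that("unbiased tracks occupy environments indistinguishable from availability", {
  s <- world_spec(seed = 11)
  fields <- gen_env_fields(s)
  tr <- gen_tracks(s, truth_suitability(), n_animals = 500,
                   mean_duration = 30, fields = fields, bias_strength = 0,
                   gap_fraction = 0)
  tp <- attr(tr, "truth_paths")
  # one (final) position per animal: independent samples
  last <- do.call(rbind, lapply(split(tp, tp$animal_id),
                                function(d) d[nrow(d), ]))
  occ <- field_lookup(fields, "sst", last$lon, last$lat,
                      as.integer(format(last$date, "%m")))
  set.seed(99)
  oc <- which(!fields$land)
  aw <- cell_areas(fields$grid)[oc]
  k <- sample(length(oc), 500, prob = aw)
  nlon <- length(fields$grid$lon)
  avail <- fields$vars$sst[cbind((oc[k] - 1) %% nlon + 1,
                                 (oc[k] - 1) %/% nlon + 1,
                                 sample(1:12, 500, TRUE))]
  p <- suppressWarnings(
    stats::ks.test(occ[!is.na(occ)], avail[!is.na(avail)])$p.value)
  expect_gt(p, 0.01)
})

test_that("strongly biased tracks occupy better-than-average habitat", {
  w <- tiny_world()
  tp <- attr(w$tracks, "truth_paths")
  n <- min(500, nrow(tp))
  set.seed(7)
  sub <- tp[sample(nrow(tp), n), ]
  mo <- as.integer(format(sub$date, "%m"))
  occ_s <- truth_value(w$truth,
                       field_lookup(w$fields, "sst", sub$lon, sub$lat, mo),
                       field_lookup(w$fields, "chl", sub$lon, sub$lat, mo))
  dom_s <- truth_value(w$truth, w$fields$vars$sst, w$fields$vars$chl)
  tt <- t.test(occ_s, mu = mean(dom_s, na.rm = TRUE), alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("climate ensemble honours size, bias and trend construction", {
  s <- spec_small()
  ce8 <- gen_climate_ensemble(s, ensemble_spec(n_models = 8))
  expect_length(ce8$models, 8)
  # every member carries all scenarios and decades
  expect_named(ce8$models[[1]]$future, c("ssp126", "ssp370", "ssp585"))
  expect_named(ce8$models[[1]]$future$ssp585,
               c("2046-2055", "2086-2095"))

  # zero bias, zero trend: future equals historical bit for bit
  ce0 <- gen_climate_ensemble(s, ensemble_spec(
    n_models = 2, per_model_bias = c(0, 0),
    scenario_deltas = list(ssp585 = list(sst = 0)), noise_sd = 0))
  expect_identical(ce0$models[[1]]$future$ssp585$`2086-2095`$sst,
                   ce0$models[[1]]$historical$sst)

  # +2 C end-of-century trend: model-mean delta = 2 within noise s.e.
  ce2 <- gen_climate_ensemble(s, ensemble_spec(
    n_models = 8, scenario_deltas = list(ssp585 = list(sst = 2)),
    noise_sd = 0.1))
  d <- vapply(ce2$models, function(m)
    mean(m$future$ssp585$`2086-2095`$sst - m$historical$sst, na.rm = TRUE), 0)
  expect_equal(mean(d), 2, tolerance = 1e-6)
})

test_that("shipping grids are non-negative, 0.2 degree, and uniform without lanes", {
  s <- spec_small()
  sh0 <- gen_shipping(s, n_lanes = 0, background = 3)
  expect_equal(sh0$grid$cell_size, 0.2)
  vals <- sh0$counts[!is.na(sh0$counts)]
  expect_true(all(vals == 3))
  sh <- gen_shipping(s, n_lanes = 3)
  expect_true(all(sh$counts[!is.na(sh$counts)] >= 0))
  expect_gt(max(sh$counts, na.rm = TRUE), 10 * min(sh$counts, na.rm = TRUE))
  expect_identical(sh$counts, gen_shipping(s, n_lanes = 3)$counts)
})

test_that("regions tile disjointly and round-trip through GeoJSON", {
  s <- spec_small()
  rg <- gen_regions(s, 4)
  expect_equal(nrow(rg), 4)
  # pairwise disjoint rectangles
  for (i in 1:3) for (j in (i + 1):4) {
    sep <- rg$lon_max[i] <= rg$lon_min[j] || rg$lon_max[j] <= rg$lon_min[i] ||
      rg$lat_max[i] <= rg$lat_min[j] || rg$lat_max[j] <= rg$lat_min[i]
    expect_true(sep)
  }
  area <- sum((rg$lon_max - rg$lon_min) * (rg$lat_max - rg$lat_min))
  expect_lte(area, diff(s$lon_range) * diff(s$lat_range) + 1e-9)

  path <- tempfile(fileext = ".geojson")
  regions_to_geojson(rg, path)
  back <- regions_from_geojson(path)
  expect_equal(as.data.frame(back), as.data.frame(rg), tolerance = 1e-12)
})
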