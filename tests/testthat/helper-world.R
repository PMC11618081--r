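# Shared fixtures, built once per test run.

# small synthetic world with a fitted model, reused across test files
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- world_spec(lon_range = c(-30, 10), lat_range = c(-36, 36),
                         seed = 42)
      truth <- truth_suitability()
      fields <- gen_env_fields(spec)
      tracks <- gen_tracks(spec, truth, n_animals = 10, mean_duration = 80,
                           fields = fields)
      daily <- process_tracks(tracks)
      pb <- build_pb_table(daily, fields, sampling_spec(seed = 42),
                           error_model())
      covs <- screen_collinearity(pb$table, pb$covariates)
      model <- fit_hab_model(pb$table, hypothesis_spec("tiny", covs))
      cache <<- list(spec = spec, truth = truth, fields = fields,
                     tracks = tracks, daily = daily, pb = pb, model = model)
    }
    cache
  }
})

# hand-built env_fields over an all-ocean grid, with per-variable generator
# functions f(lon, lat, month) -> value; used for analytic oracles
make_test_fields <- function(grid, vars = list(), static = list()) {
  nlon <- length(grid$lon); nlat <- length(grid$lat)
  lon_m <- matrix(rep(grid$lon, times = nlat), nlon, nlat)
  lat_m <- matrix(rep(grid$lat, each = nlon), nlon, nlat)
  v <- lapply(vars, function(f) {
    arr <- array(NA_real_, c(nlon, nlat, 12))
    for (m in 1:12) arr[, , m] <- f(lon_m, lat_m, m)
    arr
  })
  s <- lapply(static, function(f) f(lon_m, lat_m, 1))
  structure(list(grid = grid, months = 1:12,
                 land = matrix(FALSE, nlon, nlat),
                 vars = v, static = s, meta = list()),
            class = "env_fields")
}

# suitability_map wrapper around a bare matrix
make_test_map <- function(grid, values, label = "test") {
  structure(list(grid = grid, values = values, month = "overall",
                 label = label),
            class = "suitability_map")
}

# simple daily-track constructor
make_daily <- function(dates, lon, lat, id = "A001") {
  n <- length(lon)
  data.frame(date = as.Date(dates), lon = lon, lat = lat,
             source = rep("observed", n), animal_id = rep(id, n),
             tag_type = rep("ARGOS", n), sex = rep("F", n),
             size_m = rep(6, n), stringsAsFactors = FALSE)
}

# fixes constructor (timestamps at given UTC times)
make_fixes <- function(times, lon, lat, id = "A001", tag = "ARGOS") {
  data.frame(animal_id = id,
             timestamp = as.POSIXct(times, tz = "UTC"),
             lon = lon, lat = lat, tag_type = tag, sex = "F", size_m = 6,
             stringsAsFactors = FALSE)
}
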