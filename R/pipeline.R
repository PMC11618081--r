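# End-to-end orchestration: synthetic world -> track processing -> model
# table -> habitat model -> baseline and projected maps -> core-habitat
# change, zonal summaries and ship co-occurrence. One configuration object,
# one master seed, deterministic outputs.

#' Pipeline configuration
#'
#' All stage parameters in one validated list. Every default is the analysis
#' setting (0.25 degree grid, 100 backgrounds/day, 1:10 ratio, 40 degree crop,
#' gamma 1.4, 90th-percentile core habitat, SCI floor 0.1); the demo
#' configuration ([demo_config()]) shrinks only problem size, never rules.
#'
#' @param seed master seed; all stage substreams derive from it.
#' @param world arguments to [world_spec()] (minus seed).
#' @param truth arguments to [truth_suitability()].
#' @param tracks arguments to [gen_tracks()] (n_animals, mean_duration, ...).
#' @param sampling arguments to [sampling_spec()] (minus seed).
#' @param error arguments to [error_model()].
#' @param covariates candidate covariate names for the model.
#' @param k smooth basis size.
#' @param ensemble arguments to [ensemble_spec()].
#' @param scenarios scenario subset (default all three SSPs).
#' @param decades decade subset (default both).
#' @param q core-habitat percentile (default 90).
#' @param shipping arguments to [gen_shipping()].
#' @param n_regions number of synthetic regions.
#' @param sci_floor SCI exclusion floor (default 0.1).
#' @param evaluate run ten-fold cross-validation (default TRUE).
#' @param out_dir directory for artifacts (NULL = keep in memory only).
#' @return validated config list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            world = list(),
                            truth = list(),
                            tracks = list(),
                            sampling = list(),
                            error = list(),
                            covariates = c("sst", "chl", "sal", "bathy"),
                            k = 5,
                            ensemble = list(),
                            scenarios = c("ssp126", "ssp370", "ssp585"),
                            decades = c("2046-2055", "2086-2095"),
                            q = 90,
                            shipping = list(),
                            n_regions = 6,
                            sci_floor = 0.1,
                            evaluate = TRUE,
                            out_dir = NULL) {
  bad_sc <- setdiff(scenarios, c("ssp126", "ssp370", "ssp585"))
  if (length(bad_sc)) stop("unknown scenario key: ", paste(bad_sc, collapse = ", "))
  bad_dec <- setdiff(decades, c("2046-2055", "2086-2095"))
  if (length(bad_dec)) stop("unknown decade: ", paste(bad_dec, collapse = ", "))
  stopifnot(q > 0, q < 100, n_regions >= 1)
  cfg <- list(seed = as.integer(seed), world = world, truth = truth,
              tracks = tracks, sampling = sampling, error = error,
              covariates = covariates, k = k, ensemble = ensemble,
              scenarios = scenarios, decades = decades, q = q,
              shipping = shipping, n_regions = n_regions,
              sci_floor = sci_floor, evaluate = evaluate, out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Small-world demo configuration
#'
#' A reduced domain and track set that runs the full pipeline (baseline + two
#' scenarios x two decades) in minutes on one CPU.
#'
#' @param seed master seed.
#' @param out_dir artifact directory (NULL = in memory).
#' @return `run_config`.
#' @export
demo_config <- function(seed = 1L, out_dir = NULL) {
  pipeline_config(
    seed = seed,
    world = list(lon_range = c(-30, 10), lat_range = c(-36, 36)),
    tracks = list(n_animals = 15, mean_duration = 90),
    ensemble = list(n_models = 4),
    scenarios = c("ssp126", "ssp585"),
    evaluate = FALSE,
    out_dir = out_dir)
}

# monthly + overall maps for one field set
predict_monthly <- function(model, fields, scaling, label) {
  monthly <- lapply(1:12, function(m)
    predict_map(model, fields, scaling, month = m, label = label))
  vals <- Reduce(`+`, lapply(monthly, function(x) x$values)) / 12
  overall <- structure(list(grid = fields$grid, values = vals,
                            month = "overall", label = label),
                       class = "suitability_map")
  list(monthly = monthly, overall = overall)
}

#' Suitability at point locations
#' @param map a `suitability_map` or `sci_map`.
#' @param lon,lat coordinates.
#' @return numeric vector (NA off-grid or on land).
#' @export
map_lookup <- function(map, lon, lat) {
  idx <- cell_index(map$grid, lon, lat)
  out <- rep(NA_real_, nrow(idx))
  ok <- !is.na(idx$i) & !is.na(idx$j)
  out[ok] <- map$values[cbind(idx$i[ok], idx$j[ok])]
  out
}

write_map_csv <- function(map, path) {
  df <- grid_to_df(map$grid, map$values)
  df <- df[!is.na(df$value), ]
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes: synthetic world -> track processing -> presence-background table
#' -> habitat GAM (with pruning and optional cross-validation) -> baseline
#' monthly/overall suitability maps -> delta-change projections per
#' scenario/decade -> core-habitat areas, latitudinal shifts and zonal
#' summaries -> shipping co-occurrence change tables. Re-running with the
#' same config reproduces all numeric outputs exactly.
#'
#' @param config a `run_config`.
#' @param quiet suppress stage messages.
#' @return list of all stage outputs plus a `manifest` (config hash, seed,
#'   package version, per-stage timings).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t_all <- proc.time()[3]
  timings <- c()
  say <- function(...) if (!quiet) message(...)
  tick <- function(stage, t0) {
    timings[[stage]] <<- round(proc.time()[3] - t0, 2)
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  save_csv <- function(df, name) {
    if (!is.null(out_dir))
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }

  ## 1. synthetic world
  t0 <- proc.time()[3]
  say("stage synthworld")
  spec <- do.call(world_spec, c(config$world, list(seed = config$seed)))
  truth <- do.call(truth_suitability, config$truth)
  fields <- gen_env_fields(spec)
  tracks <- do.call(gen_tracks,
                    c(list(spec = spec, truth = truth, fields = fields),
                      config$tracks))
  shipping <- do.call(gen_shipping, c(list(spec = spec), config$shipping))
  regions <- gen_regions(spec, config$n_regions)
  if (!is.null(out_dir)) {
    save_csv(tracks, "tracks.csv")
    regions_to_geojson(regions, file.path(out_dir, "regions.geojson"))
  }
  tick("synthworld", t0)

  ## 2. track processing
  t0 <- proc.time()[3]
  say("stage trackproc")
  daily <- process_tracks(tracks)
  save_csv(daily, "daily.csv")
  tick("trackproc", t0)

  ## 3. presence-background table
  t0 <- proc.time()[3]
  say("stage bgsample")
  sspec <- do.call(sampling_spec,
                   c(config$sampling, list(seed = config$seed)))
  em <- do.call(error_model, config$error)
  pb <- build_pb_table(daily, fields, sspec, em)
  save_csv(pb$table, "pbtable.csv")
  tick("bgsample", t0)

  ## 4. habitat model
  t0 <- proc.time()[3]
  say("stage habmodel")
  covs <- screen_collinearity(pb$table, intersect(config$covariates,
                                                  pb$covariates))
  hyp <- hypothesis_spec("main", covs, k = config$k)
  model <- fit_hab_model(pb$table, hyp)
  model <- prune_nonsignificant(model, pb$table)
  eval_res <- NULL
  if (isTRUE(config$evaluate)) {
    eval_res <- evaluate_cv(pb$table, model$hyp, seed = config$seed)
    save_csv(data.frame(metric = names(eval_res$metrics),
                        value = as.numeric(eval_res$metrics)),
             "cv_metrics.csv")
  }
  baseline <- predict_monthly(model, fields, pb$scaling, "baseline")
  fav <- favourability(baseline$overall, model$prevalence)
  if (!is.null(out_dir)) {
    write_map_csv(baseline$overall,
                  file.path(out_dir, "suitability_baseline.csv"))
    write_map_csv(fav, file.path(out_dir, "favourability_baseline.csv"))
  }
  tick("habmodel", t0)

  ## 5. climate projection
  t0 <- proc.time()[3]
  say("stage climproj")
  ens <- do.call(ensemble_spec, config$ensemble)
  ensemble <- gen_climate_ensemble(spec, ens)
  keys <- list()
  for (sc in config$scenarios)
    for (dec in config$decades)
      keys[[paste(sc, dec, sep = "_")]] <- scenario_key(sc, dec)
  projected <- lapply(keys, function(key) {
    flds <- project_fields(fields, ensemble, key)
    predict_monthly(model, flds, pb$scaling,
                    paste(key$scenario, key$decade, sep = "_"))
  })
  tick("climproj", t0)

  ## 6. habitat change
  t0 <- proc.time()[3]
  say("stage habchange")
  core_base <- core_threshold(baseline$overall, q = config$q)
  change_rows <- list()
  summaries <- list(zonal_summary(baseline$overall, core_base, regions,
                                  period = "baseline"))
  for (nm in names(projected)) {
    key <- keys[[nm]]
    fut <- projected[[nm]]$overall
    core_within <- core_threshold(fut, q = config$q, mode = "within_map")
    core_baselined <- core_threshold(fut, q = config$q,
                                     mode = "baseline_threshold",
                                     baseline_map = baseline$overall)
    ey <- elapsed_years_for(key$decade)
    shift <- latitudinal_shift(core_base, core_within, ey)
    change_rows[[nm]] <- data.frame(
      scenario = key$scenario, decade = key$decade,
      area_change_km2_baseline_thr = habitat_area_change(core_base,
                                                         core_baselined),
      area_change_km2_within_map = habitat_area_change(core_base, core_within),
      north_shift_km = shift$shift_km[shift$edge == "north"],
      south_shift_km = shift$shift_km[shift$edge == "south"],
      north_rate_km_yr = shift$rate_km_yr[shift$edge == "north"])
    summaries[[nm]] <- zonal_summary(fut, core_within, regions, period = nm)
  }
  habitat_change <- do.call(rbind, change_rows)
  rownames(habitat_change) <- NULL
  region_summaries <- do.call(rbind, summaries)
  monthly_base <- monthly_summary(baseline$monthly, regions)
  save_csv(habitat_change, "habitat_change.csv")
  save_csv(region_summaries, "region_summaries.csv")
  save_csv(monthly_base, "monthly_suitability.csv")
  tick("habchange", t0)

  ## 7. ship co-occurrence
  t0 <- proc.time()[3]
  say("stage shipco")
  ship_analysis <- regrid_shipping(shipping, fields$grid)
  norm <- max(ship_analysis, na.rm = TRUE)
  sci_base <- sci_map(baseline$overall, ship_analysis, norm)
  base_means <- sci_region_means(sci_base, regions)
  sci_tables <- list()
  for (nm in names(projected)) {
    sci_fut <- sci_map(projected[[nm]]$overall, ship_analysis, norm)
    ch <- sci_change(base_means, sci_region_means(sci_fut, regions),
                     floor = config$sci_floor)
    tab <- ch$table
    tab$scenario <- keys[[nm]]$scenario
    tab$decade <- keys[[nm]]$decade
    tab$mean_fold_change <- ch$mean_fold_change
    tab$pct_change_of_mean <- ch$pct_change_of_mean
    sci_tables[[nm]] <- tab
  }
  sci_change_table <- do.call(rbind, sci_tables)
  rownames(sci_change_table) <- NULL
  save_csv(sci_change_table, "sci_change.csv")
  tick("shipco", t0)

  manifest <- list(
    config_hash = rlang::hash(unclass(config)[setdiff(names(config),
                                                      "out_dir")]),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("pelagicshift")),
    n_presences = sum(pb$table$label == 1),
    n_rows = nrow(pb$table),
    covariates_fitted = model$hyp$covariates,
    timings_s = as.list(timings),
    total_s = round(proc.time()[3] - t_all, 2))
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)

  list(spec = spec, truth = truth, fields = fields, tracks = tracks,
       daily = daily, pb = pb, model = model, evaluation = eval_res,
       baseline = baseline, favourability = fav, ensemble = ensemble,
       projected = projected, core_baseline = core_base,
       habitat_change = habitat_change, region_summaries = region_summaries,
       monthly_suitability = monthly_base, regions = regions,
       shipping = shipping, sci_baseline = sci_base,
       sci_change = sci_change_table, manifest = manifest)
}
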