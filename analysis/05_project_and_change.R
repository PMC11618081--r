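# 05 - Predict baseline suitability, project it under three SSPs x two
# decades through the delta-change ensemble, and quantify core-habitat
# (90th percentile) area change, latitudinal limit shifts and per-region
# summaries.

source("analysis/00_config.R")

fields <- fields_of(CFG)
tab <- read.csv(file.path(RESULTS, "pbtable.csv"))
tab$date <- as.Date(tab$date)
scaling <- jsonlite::read_json(file.path(RESULTS, "scaling.json"),
                               simplifyVector = TRUE)
regions <- regions_from_geojson(file.path(RESULTS, "regions.geojson"))

covs <- screen_collinearity(tab, intersect(CFG$covariates, names(tab)))
model <- prune_nonsignificant(fit_hab_model(tab, hypothesis_spec("full", covs)),
                              tab)

baseline <- predict_map(model, fields, scaling, month = "overall",
                        label = "baseline")
core_base <- core_threshold(baseline, q = CFG$q)
message(sprintf("baseline core habitat (q=%d): %.2f million km2 at threshold %.3f",
                CFG$q, core_area_km2(core_base) / 1e6, core_base$threshold))

ensemble <- gen_climate_ensemble(world_of(CFG),
                                 do.call(ensemble_spec, CFG$ensemble))
rows <- list(); summaries <- list(
  zonal_summary(baseline, core_base, regions, period = "baseline"))
for (sc in CFG$scenarios) for (dec in CFG$decades) {
  key <- scenario_key(sc, dec)
  fut <- predict_map(model, project_fields(fields, ensemble, key), scaling,
                     month = "overall", label = paste(sc, dec, sep = "_"))
  core_fut <- core_threshold(fut, q = CFG$q)
  sh <- latitudinal_shift(core_base, core_fut, elapsed_years_for(dec))
  rows[[paste(sc, dec)]] <- data.frame(
    scenario = sc, decade = dec,
    area_change_km2 = habitat_area_change(core_base, core_fut),
    north_shift_km = sh$shift_km[sh$edge == "north"],
    north_rate_km_yr = sh$rate_km_yr[sh$edge == "north"],
    south_shift_km = sh$shift_km[sh$edge == "south"])
  summaries[[paste(sc, dec)]] <- zonal_summary(fut, core_fut, regions,
                                               period = paste(sc, dec, sep = "_"))
  message(sprintf("%s %s: area change %+.2f Mkm2, north edge %+.0f km (%.2f km/yr)",
                  sc, dec, rows[[paste(sc, dec)]]$area_change_km2 / 1e6,
                  rows[[paste(sc, dec)]]$north_shift_km,
                  rows[[paste(sc, dec)]]$north_rate_km_yr))
}

write.csv(do.call(rbind, rows), file.path(RESULTS, "habitat_change.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, summaries), file.path(RESULTS, "region_summaries.csv"),
          row.names = FALSE)
df <- data.frame(lon = rep(baseline$grid$lon, length(baseline$grid$lat)),
                 lat = rep(baseline$grid$lat, each = length(baseline$grid$lon)),
                 suitability = as.vector(baseline$values))
write.csv(df[!is.na(df$suitability), ],
          file.path(RESULTS, "suitability_baseline.csv"), row.names = FALSE)
message("wrote habitat_change.csv, region_summaries.csv, suitability_baseline.csv")
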