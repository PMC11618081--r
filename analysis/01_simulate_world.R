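# 01 - Simulate the synthetic world: environmental fields, tagged animal
# tracks with a known thermal niche (optimum 27 C, tolerance 3 C), a
# lane-structured shipping grid and rectangular stand-in regions.

source("analysis/00_config.R")

spec <- world_of(CFG)
truth <- truth_suitability()          # 27 C optimum, 3 C tolerance
fields <- fields_of(CFG)
message(sprintf("world: %d x %d cells, SST %.1f-%.1f C",
                length(spec$grid$lon), length(spec$grid$lat),
                min(fields$vars$sst, na.rm = TRUE),
                max(fields$vars$sst, na.rm = TRUE)))

tracks <- do.call(gen_tracks, c(list(spec = spec, truth = truth,
                                     fields = fields), CFG$tracks))
message(sprintf("tracks: %d fixes from %d animals (%.0f%% PSAT)",
                nrow(tracks), length(unique(tracks$animal_id)),
                100 * mean(tapply(tracks$tag_type, tracks$animal_id,
                                  function(x) x[1]) == "PSAT")))

shipping <- do.call(gen_shipping, c(list(spec = spec), CFG$shipping))
regions <- gen_regions(spec, CFG$n_regions)

write.csv(tracks, file.path(RESULTS, "tracks.csv"), row.names = FALSE)
ship_df <- data.frame(lon = rep(shipping$grid$lon, length(shipping$grid$lat)),
                      lat = rep(shipping$grid$lat, each = length(shipping$grid$lon)),
                      vessels = as.vector(shipping$counts))
write.csv(ship_df[!is.na(ship_df$vessels), ],
          file.path(RESULTS, "shipping_02deg.csv"), row.names = FALSE)
regions_to_geojson(regions, file.path(RESULTS, "regions.geojson"))
message("wrote tracks.csv, shipping_02deg.csv, regions.geojson")
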