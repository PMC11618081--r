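# 02 - Regularize raw fixes into daily positions: floating-device tails cut,
# one position per UTC day, gaps of up to 3 days interpolated, then thinned
# to >= 2-day separation for modelling.

source("analysis/00_config.R")

tracks <- read.csv(file.path(RESULTS, "tracks.csv"))
tracks$timestamp <- as.POSIXct(tracks$timestamp, tz = "UTC")

daily <- process_tracks(tracks)
daily_unthinned <- process_tracks(tracks, thin = FALSE)

message(sprintf("%d fixes -> %d regularized daily positions -> %d model days",
                nrow(tracks), nrow(daily_unthinned), nrow(daily)))
message(sprintf("interpolated share of daily track: %.1f%%",
                100 * mean(daily_unthinned$source == "interpolated")))

write.csv(daily, file.path(RESULTS, "daily.csv"), row.names = FALSE)
write.csv(daily_unthinned, file.path(RESULTS, "daily_unthinned.csv"),
          row.names = FALSE)
message("wrote daily.csv, daily_unthinned.csv")
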