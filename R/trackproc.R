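# Track processing: raw satellite fixes -> regularized daily positions.
# Inputs are assumed already speed/error filtered upstream; these routines
# handle floating-device removal, daily averaging, short-gap interpolation
# and autocorrelation thinning.

# circular mean of longitudes in degrees, result in [-180, 180)
circ_mean_lon <- function(lon) {
  r <- lon * pi / 180
  m <- atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
  ((m + 180) %% 360) - 180
}

#' Detect a trailing floating-device segment
#'
#' Scans the daily-averaged track backwards for a trailing run of consecutive
#' transmitting days whose day-to-day great-circle displacement stays below
#' `displacement_threshold`; a run of at least `window` days flags the tag as
#' detached and floating. Thresholds are heuristics (tag-detachment behaviour
#' is assessed case by case in practice) and are deliberately exposed.
#'
#' @param track data.frame of fixes with `timestamp`, `lon`, `lat` (one animal).
#' @param window minimum run length in days (default 14).
#' @param displacement_threshold km/day below which a day counts as
#'   stationary (default 5).
#' @return the `Date` on which the floating run starts, or `NULL` if none.
#' @export
detect_floating_tail <- function(track, window = 14,
                                 displacement_threshold = 5) {
  daily <- regularize_daily(track)
  if (nrow(daily) < window) stop("need at least `window` days of data")
  n <- nrow(daily)
  disp <- gc_dist_km(daily$lon[-n], daily$lat[-n], daily$lon[-1], daily$lat[-1])
  consec <- as.numeric(diff(daily$date)) == 1
  # stationary[k]: step into day k+1 is consecutive and below threshold
  stationary <- consec & (disp < displacement_threshold)
  run <- 0L
  for (k in n:2) {
    if (stationary[k - 1L]) run <- run + 1L else break
  }
  if (run + 1L >= window) daily$date[n - run] else NULL
}

#' Regularize a track to one position per day
#'
#' Averages all fixes within each UTC calendar date: arithmetic mean latitude,
#' circular mean longitude (fixes straddling the antimeridian average
#' correctly).
#'
#' @param track data.frame of fixes for one animal: `timestamp` (POSIXct UTC),
#'   `lon`, `lat`, and optional metadata columns (`animal_id`, `tag_type`,
#'   `sex`, `size_m`) carried through.
#' @return data.frame with one row per date: `date`, `lon`, `lat`,
#'   `source = "observed"`, plus metadata.
#' @export
regularize_daily <- function(track) {
  meta_cols <- intersect(c("animal_id", "tag_type", "sex", "size_m"),
                         names(track))
  if (nrow(track) == 0) {
    out <- data.frame(date = as.Date(character()), lon = numeric(),
                      lat = numeric(), source = character())
    for (mc in meta_cols) out[[mc]] <- track[[mc]][0]
    return(out)
  }
  stopifnot(!is.unsorted(track$timestamp))
  date <- as.Date(track$timestamp, tz = "UTC")
  lon <- tapply(track$lon, date, circ_mean_lon)
  lat <- tapply(track$lat, date, mean)
  out <- data.frame(date = as.Date(names(lon)), lon = as.numeric(lon),
                    lat = as.numeric(lat), source = "observed",
                    stringsAsFactors = FALSE)
  for (mc in meta_cols) out[[mc]] <- track[[mc]][1]
  out[order(out$date), , drop = FALSE]
}

#' Fill short gaps in a daily track by linear interpolation
#'
#' Gaps of 1 to `max_gap` missing calendar days between observed positions are
#' filled by linear interpolation in lon/lat and flagged
#' `source = "interpolated"`; longer gaps are left missing. Interpolation is
#' planar, adequate for the short gaps it is restricted to.
#'
#' @param dt a daily track from [regularize_daily()].
#' @param max_gap maximum number of consecutive missing days to fill
#'   (default 3).
#' @return daily track with interpolated rows inserted.
#' @export
interpolate_gaps <- function(dt, max_gap = 3) {
  if (nrow(dt) < 2) return(dt)
  meta_cols <- intersect(c("animal_id", "tag_type", "sex", "size_m"), names(dt))
  pieces <- list(dt[1, , drop = FALSE])
  for (k in 2:nrow(dt)) {
    gap <- as.numeric(dt$date[k] - dt$date[k - 1]) - 1
    if (gap >= 1 && gap <= max_gap) {
      f <- seq_len(gap) / (gap + 1)
      fill <- data.frame(date = dt$date[k - 1] + seq_len(gap),
                         lon = dt$lon[k - 1] + f * (dt$lon[k] - dt$lon[k - 1]),
                         lat = dt$lat[k - 1] + f * (dt$lat[k] - dt$lat[k - 1]),
                         source = "interpolated", stringsAsFactors = FALSE)
      for (mc in meta_cols) fill[[mc]] <- dt[[mc]][1]
      pieces[[length(pieces) + 1]] <- fill[names(dt)]
    }
    pieces[[length(pieces) + 1]] <- dt[k, , drop = FALSE]
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Thin a daily track for model fitting
#'
#' Greedy forward pass keeping a day only if it is at least `min_separation`
#' days after the last kept day, removing consecutive daily locations to
#' reduce serial autocorrelation in the fitting data. Interpolated positions
#' are dropped first (`observed_only = TRUE`): invented positions should not
#' enter the model as presences, and this makes the processing pipeline a
#' fixed point of itself.
#'
#' @param dt a daily track.
#' @param min_separation minimum day gap between kept locations (default 2).
#' @param observed_only restrict to `source == "observed"` rows (default TRUE;
#'   rows without a `source` column are treated as observed).
#' @return thinned daily track.
#' @export
thin_for_model <- function(dt, min_separation = 2, observed_only = TRUE) {
  if (observed_only && !is.null(dt$source))
    dt <- dt[dt$source == "observed", , drop = FALSE]
  if (nrow(dt) == 0) return(dt)
  keep <- logical(nrow(dt))
  keep[1] <- TRUE
  last <- dt$date[1]
  for (k in seq_len(nrow(dt))[-1]) {
    if (as.numeric(dt$date[k] - last) >= min_separation) {
      keep[k] <- TRUE
      last <- dt$date[k]
    }
  }
  out <- dt[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full track-processing pipeline over a multi-animal fix table
#'
#' Per animal: cut any detected floating tail, regularize to daily positions,
#' interpolate short gaps, and (optionally) thin. The thinned track is what
#' the model sees; the unthinned daily track drives background sampling.
#'
#' @param tracks fix table from [gen_tracks()] or read from CSV.
#' @param max_gap,min_separation see [interpolate_gaps()], [thin_for_model()].
#' @param float_window,float_threshold see [detect_floating_tail()]; set
#'   `float_window = NULL` to skip detection.
#' @param thin apply the thinning pass (default TRUE).
#' @return daily track table over all animals.
#' @export
process_tracks <- function(tracks, max_gap = 3, min_separation = 2,
                           float_window = 14, float_threshold = 5,
                           thin = TRUE) {
  out <- lapply(split(tracks, tracks$animal_id), function(tr) {
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    if (!is.null(float_window) &&
        length(unique(as.Date(tr$timestamp, tz = "UTC"))) >= float_window) {
      cut <- detect_floating_tail(tr, float_window, float_threshold)
      if (!is.null(cut))
        tr <- tr[as.Date(tr$timestamp, tz = "UTC") < cut, , drop = FALSE]
    }
    if (nrow(tr) == 0) return(NULL)
    dt <- interpolate_gaps(regularize_daily(tr), max_gap)
    if (thin) dt <- thin_for_model(dt, min_separation)
    dt
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
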