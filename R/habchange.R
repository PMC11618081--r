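# Core-habitat definition and redistribution metrics: percentile thresholds,
# spherical areas, latitudinal limit shifts, change classification, zonal and
# monthly summaries within region polygons.

KM_PER_DEG_LAT <- 111.32

#' Core habitat from a suitability percentile
#'
#' Core habitat is the set of ocean cells at or above the `q`-th percentile of
#' suitability. `mode = "within_map"` takes the percentile from the map itself
#' (where have the most important areas moved); `mode = "baseline_threshold"`
#' takes it from a designated baseline map and applies it to this map (how
#' much current-quality habitat remains).
#'
#' @param map a `suitability_map`.
#' @param q percentile in (0, 100); default 90, sensitivity set {50, 75, 95}.
#' @param mode threshold source.
#' @param baseline_map reference map for `mode = "baseline_threshold"`.
#' @return object of class `core_habitat`: logical `[lon, lat]` mask,
#'   threshold, percentile and mode.
#' @export
core_threshold <- function(map, q = 90,
                           mode = c("within_map", "baseline_threshold"),
                           baseline_map = NULL) {
  mode <- match.arg(mode)
  ref <- if (mode == "within_map") map else {
    stopifnot(!is.null(baseline_map))
    baseline_map
  }
  ref_vals <- ref$values[!is.na(ref$values)]
  if (length(ref_vals) < 10) stop("need at least 10 ocean cells")
  thr <- stats::quantile(ref_vals, q / 100, type = 7, names = FALSE)
  mask <- !is.na(map$values) & map$values >= thr
  structure(list(mask = mask, threshold = thr, q = q, mode = mode,
                 grid = map$grid, label = map$label),
            class = "core_habitat")
}

#' Total area of a core-habitat mask
#' @param core a `core_habitat`.
#' @return area in km^2.
#' @export
core_area_km2 <- function(core) {
  sum(cell_areas(core$grid)[core$mask])
}

#' Change in core-habitat area
#'
#' @param current,future `core_habitat` masks on a common grid.
#' @return future minus current area, km^2.
#' @export
habitat_area_change <- function(current, future) {
  stopifnot(identical(dim(current$mask), dim(future$mask)))
  core_area_km2(future) - core_area_km2(current)
}

#' Latitudinal shift of core-habitat limits
#'
#' North/south limits are the extreme cell-centre latitudes of the mask.
#' Edge shifts are in km (`KM_PER_DEG_LAT` = 111.32 km per degree), signed so
#' that positive means movement toward the nearer pole: northward for the
#' north edge, southward for the south edge. Rates divide by the elapsed
#' years between period midpoints.
#'
#' @param current,future non-empty `core_habitat` masks on a common grid.
#' @param elapsed_years elapsed time between period midpoints (> 0).
#' @return object of class `shift_report` (data.frame, one row per edge).
#' @export
latitudinal_shift <- function(current, future, elapsed_years) {
  stopifnot(elapsed_years > 0)
  lims <- function(core) {
    j <- which(apply(core$mask, 2, any))
    if (length(j) == 0) stop("empty core-habitat mask")
    range(core$grid$lat[j])
  }
  cur <- lims(current); fut <- lims(future)
  north_km <- (fut[2] - cur[2]) * KM_PER_DEG_LAT   # + = northward
  south_km <- (cur[1] - fut[1]) * KM_PER_DEG_LAT   # + = southward
  out <- data.frame(
    edge = c("north", "south"),
    current_limit = c(cur[2], cur[1]),
    future_limit = c(fut[2], fut[1]),
    shift_km = c(north_km, south_km),
    rate_km_yr = c(north_km, south_km) / elapsed_years,
    elapsed_years = elapsed_years)
  class(out) <- c("shift_report", "data.frame")
  out
}

#' Midpoint-to-midpoint elapsed years for a decade
#'
#' Baseline midpoint defaults to 2012 (centre of 2005-2019); decade midpoints
#' are 2050.5 and 2090.5.
#'
#' @param decade "2046-2055" or "2086-2095".
#' @param baseline_mid baseline period midpoint (default 2012).
#' @return elapsed years.
#' @export
elapsed_years_for <- function(decade, baseline_mid = 2012) {
  mid <- c(`2046-2055` = 2050.5, `2086-2095` = 2090.5)[[decade]]
  mid - baseline_mid
}

#' Cellwise suitability change and its classification
#'
#' @param current,future `suitability_map`s on a common grid.
#' @param classify_threshold |delta| beyond which a cell is classed as change
#'   (default 0.5, strict inequality).
#' @return list: `delta` matrix (future - current) and `class` character
#'   matrix in {"increase", "decrease", "no_change"}.
#' @export
change_map <- function(current, future, classify_threshold = 0.5) {
  stopifnot(identical(dim(current$values), dim(future$values)))
  delta <- future$values - current$values
  cls <- matrix(NA_character_, nrow(delta), ncol(delta))
  ok <- !is.na(delta)
  cls[ok] <- "no_change"
  cls[ok & delta > classify_threshold] <- "increase"
  cls[ok & delta < -classify_threshold] <- "decrease"
  list(delta = delta, class = cls)
}

# logical [lon, lat] membership matrix of a rectangular region (cell centres;
# max edges half-open so a disjoint tiling stays disjoint on the grid)
region_mask <- function(grid, region_row) {
  lon_in <- grid$lon >= region_row$lon_min & grid$lon < region_row$lon_max
  lat_in <- grid$lat >= region_row$lat_min & grid$lat < region_row$lat_max
  outer(lon_in, lat_in, FUN = "&")
}

#' Zonal summary of suitability and core coverage per region
#'
#' Per region: area-weighted mean suitability over ocean cells whose centres
#' fall inside the polygon, and core-habitat coverage as percent of the
#' region's ocean area.
#'
#' @param map a `suitability_map`.
#' @param core a `core_habitat` on the same grid (NULL skips coverage).
#' @param regions a `region_set`.
#' @param period label copied to the output.
#' @return data.frame: region_id, mean_suitability, core_coverage_pct,
#'   ocean_area_km2, period. Regions with no ocean cells get NA.
#' @export
zonal_summary <- function(map, core, regions, period = map$label) {
  areas <- cell_areas(map$grid)
  ocean <- !is.na(map$values)
  rows <- lapply(seq_len(nrow(regions)), function(k) {
    inreg <- region_mask(map$grid, regions[k, ]) & ocean
    if (!any(inreg))
      return(data.frame(region_id = regions$region_id[k],
                        mean_suitability = NA_real_,
                        core_coverage_pct = NA_real_,
                        ocean_area_km2 = 0, period = period))
    a <- areas[inreg]
    ms <- sum(map$values[inreg] * a) / sum(a)
    cov <- if (is.null(core)) NA_real_ else
      100 * sum(areas[inreg & core$mask]) / sum(a)
    data.frame(region_id = regions$region_id[k], mean_suitability = ms,
               core_coverage_pct = cov, ocean_area_km2 = sum(a),
               period = period)
  })
  do.call(rbind, rows)
}

#' Monthly mean suitability per region
#'
#' @param monthly_maps list of 12 `suitability_map`s (months 1-12).
#' @param regions a `region_set`.
#' @return data.frame month x region of area-weighted mean suitability, plus
#'   an `annual` row equal to the mean of the 12 monthly means.
#' @export
monthly_summary <- function(monthly_maps, regions) {
  if (length(monthly_maps) != 12) stop("need 12 monthly maps")
  tabs <- lapply(1:12, function(m) {
    z <- zonal_summary(monthly_maps[[m]], core = NULL, regions,
                       period = as.character(m))
    data.frame(month = m, region_id = z$region_id,
               mean_suitability = z$mean_suitability)
  })
  out <- do.call(rbind, tabs)
  ann <- stats::aggregate(mean_suitability ~ region_id, out, mean)
  ann$month <- NA_integer_
  rbind(out, ann[, c("month", "region_id", "mean_suitability")])
}
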