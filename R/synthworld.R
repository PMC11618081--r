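#' Synthetic-world specification
#'
#' Describes the domain every generator shares: the analysis grid, the monthly
#' time axis and the baseline period. All generators are deterministic given
#' `seed` (expanded internally into independent per-component substreams).
#'
#' @param lon_range,lat_range domain extent, degrees.
#' @param cell_size analysis resolution in degrees (default 0.25).
#' @param months number of months in the climatology (>= 12; default 12).
#' @param baseline_years length-2 integer vector (default 2005-2019).
#' @param seed integer master seed.
#' @return object of class `world_spec`.
#' @export
world_spec <- function(lon_range = c(-40, 10), lat_range = c(-45, 45),
                       cell_size = 0.25, months = 12,
                       baseline_years = c(2005, 2019), seed = 1L) {
  stopifnot(cell_size > 0, months >= 12,
            lat_range[1] >= -90, lat_range[2] <= 90,
            baseline_years[1] <= baseline_years[2])
  grid <- make_grid(lon_range, lat_range, cell_size)  # validates the extent
  structure(list(lon_range = lon_range, lat_range = lat_range,
                 cell_size = cell_size, months = as.integer(months),
                 baseline_years = as.integer(baseline_years),
                 seed = as.integer(seed), grid = grid),
            class = "world_spec")
}

#' Ground-truth suitability parameters
#'
#' The niche the synthetic animals follow: a Gaussian thermal band around
#' `sst_optimum` plus a log-chlorophyll preference, on the logit scale.
#' Downstream parameter-recovery tests ask the fitted model to find
#' `sst_optimum` back.
#'
#' @param sst_optimum thermal optimum, deg C.
#' @param sst_tolerance thermal niche width (Gaussian sd), deg C; > 0.
#' @param chl_coefficient coefficient on log chlorophyll (unitless).
#' @param intercept logit-scale intercept.
#' @return object of class `truth_suitability`.
#' @export
truth_suitability <- function(sst_optimum = 27, sst_tolerance = 3,
                              chl_coefficient = 0.5, intercept = 0.5) {
  stopifnot(sst_tolerance > 0)
  structure(list(sst_optimum = sst_optimum, sst_tolerance = sst_tolerance,
                 chl_coefficient = chl_coefficient, intercept = intercept),
            class = "truth_suitability")
}

#' Evaluate ground-truth suitability
#'
#' @param truth a `truth_suitability`.
#' @param sst,chl environmental values (vectorized).
#' @param link return the logit (`"logit"`) or probability (`"response"`).
#' @return numeric vector.
#' @export
truth_value <- function(truth, sst, chl, link = c("response", "logit")) {
  link <- match.arg(link)
  lp <- truth$intercept + truth$chl_coefficient * log(chl) -
    ((sst - truth$sst_optimum) / truth$sst_tolerance)^2
  if (link == "logit") lp else stats::plogis(lp)
}

# Closed-form (noise-free) SST surface: meridional gradient plus a seasonal
# sinusoid whose amplitude grows away from the equator and whose phase flips
# between hemispheres (warmest Aug north, Feb south).
#' @export
#' @rdname gen_env_fields
sst_closed_form <- function(lat, month, pars = list(equator_sst = 29,
                                                    pole_drop = 14,
                                                    gradient_power = 1.5,
                                                    seasonal_amp = 3,
                                                    lat_scale = 45)) {
  base <- pars$equator_sst -
    pars$pole_drop * (abs(lat) / pars$lat_scale)^pars$gradient_power
  amp <- pars$seasonal_amp * pmin(abs(lat), 30) / 30
  peak <- ifelse(lat >= 0, 8, 2)                    # warmest month by hemisphere
  base + amp * cos(2 * pi * (month - peak) / 12)
}

#' Generate gridded environmental fields
#'
#' Builds a monthly climatology of essential ocean variables on the spec grid:
#' SST (meridional gradient + seasonal sinusoid + noise), chlorophyll
#' (coastal exponential decay, strictly positive, lognormal noise), salinity
#' (subtropical maxima) and a static bathymetry. A synthetic coast occupies the
#' western `land_fraction` of the domain; land cells are NA in every variable.
#'
#' @param spec a `world_spec`.
#' @param noise_sd named list of noise amplitudes per variable (sd of additive
#'   noise for sst/sal, sd of log-scale noise for chl). Zero gives the
#'   closed-form surfaces exactly.
#' @param land_fraction fraction of the longitudinal extent that is land
#'   (west side).
#' @param pars parameters of the closed-form SST surface (see
#'   [sst_closed_form()]).
#' @return object of class `env_fields`: grid, land mask, monthly variable
#'   arrays `[lon, lat, month]` in `$vars` and static matrices in `$static`.
#' @export
gen_env_fields <- function(spec,
                           noise_sd = list(sst = 0.3, chl = 0.25, sal = 0.1),
                           land_fraction = 0.1,
                           pars = NULL) {
  stopifnot(inherits(spec, "world_spec"))
  if (is.null(pars))
    pars <- list(equator_sst = 29, pole_drop = 14, gradient_power = 1.5,
                 seasonal_amp = 3, lat_scale = max(abs(spec$lat_range)))
  grid <- spec$grid
  nlon <- length(grid$lon); nlat <- length(grid$lat); nm <- spec$months
  set.seed(substream_seed(spec$seed, "env"))

  meridian <- grid$lon_range[1] + land_fraction * diff(grid$lon_range)
  land <- matrix(grid$lon < meridian, nlon, nlat)
  dist_coast <- pmax(outer(grid$lon - meridian, rep(1, nlat)), 0)  # deg east of coast

  month_of <- function(m) ((m - 1) %% 12) + 1

  sst <- array(NA_real_, c(nlon, nlat, nm))
  chl <- array(NA_real_, c(nlon, nlat, nm))
  sal <- array(NA_real_, c(nlon, nlat, nm))
  for (m in seq_len(nm)) {
    mo <- month_of(m)
    sst_m <- matrix(rep(sst_closed_form(grid$lat, mo, pars), each = nlon),
                    nlon, nlat)
    if (noise_sd$sst > 0)
      sst_m <- sst_m + matrix(stats::rnorm(nlon * nlat, 0, noise_sd$sst),
                              nlon, nlat)
    chl_m <- (0.05 + 2.5 * exp(-dist_coast / 4)) *
      (1 + 0.3 * cos(2 * pi * (mo - 3) / 12))
    if (noise_sd$chl > 0)
      chl_m <- chl_m * exp(matrix(stats::rnorm(nlon * nlat, 0, noise_sd$chl),
                                  nlon, nlat))
    sal_m <- 34 +
      1.5 * exp(-((abs(matrix(rep(grid$lat, each = nlon), nlon, nlat)) - 25) / 12)^2)
    if (noise_sd$sal > 0)
      sal_m <- sal_m + matrix(stats::rnorm(nlon * nlat, 0, noise_sd$sal),
                              nlon, nlat)
    sst_m[land] <- NA; chl_m[land] <- NA; sal_m[land] <- NA
    sst[, , m] <- sst_m; chl[, , m] <- chl_m; sal[, , m] <- sal_m
  }
  bathy <- -(20 + 4500 * (1 - exp(-dist_coast / 6)))
  bathy[land] <- NA

  structure(list(grid = grid, months = seq_len(nm), land = land,
                 vars = list(sst = sst, chl = chl, sal = sal),
                 static = list(bathy = bathy),
                 meta = list(meridian = meridian, pars = pars,
                             baseline_years = spec$baseline_years)),
            class = "env_fields")
}

#' @export
print.env_fields <- function(x, ...) {
  cat(sprintf("<env_fields> %d x %d grid, %d months, vars: %s; static: %s\n",
              length(x$grid$lon), length(x$grid$lat), length(x$months),
              paste(names(x$vars), collapse = ", "),
              paste(names(x$static), collapse = ", ")))
  invisible(x)
}

# Nearest-cell lookup of a monthly variable at point locations.
#' Look up field values at point locations
#' @param fields an `env_fields`.
#' @param var variable name in `fields$vars` or `fields$static`.
#' @param lon,lat,month query vectors (month ignored for static variables).
#' @return numeric vector (NA on land / outside the grid).
#' @export
field_lookup <- function(fields, var, lon, lat, month = NULL) {
  idx <- cell_index(fields$grid, lon, lat)
  n <- nrow(idx)
  out <- rep(NA_real_, n)
  ok <- !is.na(idx$i) & !is.na(idx$j)
  if (var %in% names(fields$static)) {
    out[ok] <- fields$static[[var]][cbind(idx$i[ok], idx$j[ok])]
    return(out)
  }
  stopifnot(var %in% names(fields$vars), !is.null(month))
  month <- rep_len(as.integer(month), n)
  arr <- fields$vars[[var]]
  out[ok] <- arr[cbind(idx$i[ok], idx$j[ok], month[ok])]
  out
}

# Tag-type positional error radii (degrees), per axis.
tag_error_sigma <- function(tag_type) {
  switch(tag_type,
         ARGOS = c(lon = 0.12, lat = 0.12),
         PSAT  = c(lon = 0.53, lat = 1.08),
         stop("unknown tag type: ", tag_type))
}

#' Generate biased-random-walk telemetry tracks
#'
#' Daily-step movement where each candidate step (uniform heading, half-normal
#' length) is accepted with probability `plogis(bias_strength * truth logit)`
#' at the candidate cell, so occupied habitat concentrates around the
#' ground-truth niche; `bias_strength = 0` gives unbiased movement. Fixes get
#' tag-specific positional error (ARGOS 0.12/0.12 deg, PSAT 1.08 lat/0.53 lon),
#' geometric transmission gaps (about `gap_fraction` of days missing), and
#' optionally a trailing "floating device" segment of near-zero displacement.
#'
#' @param spec a `world_spec`.
#' @param truth a `truth_suitability`.
#' @param n_animals number of animals (>= 1).
#' @param mean_duration mean track length, days.
#' @param fields optional pre-generated `env_fields` (regenerated otherwise).
#' @param bias_strength multiplier on the truth logit in the step-acceptance
#'   probability; 0 = no habitat preference.
#' @param gap_fraction target fraction of days with no transmission.
#' @param mean_gap_len mean transmission-gap length, days.
#' @param floating_prob probability an animal's tag detaches and floats for
#'   `floating_days` at the end of its record.
#' @param floating_days length of the injected floating tail.
#' @param psat_prob probability a tag is PSAT rather than ARGOS.
#' @param step_sd scale of daily step length, degrees.
#' @return data.frame of fixes (`animal_id`, `timestamp` POSIXct UTC, `lon`,
#'   `lat`, `tag_type`, `sex`, `size_m`) with attributes `truth_paths` (true
#'   daily positions) and `floating_start` (named Date vector of injected
#'   detachment dates).
#' @export
gen_tracks <- function(spec, truth, n_animals = 30, mean_duration = 120,
                       fields = NULL, bias_strength = 4,
                       gap_fraction = 0.2, mean_gap_len = 2,
                       floating_prob = 0, floating_days = 20,
                       psat_prob = 0.3, step_sd = 0.7, seed = spec$seed) {
  stopifnot(inherits(spec, "world_spec"), inherits(truth, "truth_suitability"),
            n_animals >= 1)
  if (is.null(fields)) fields <- gen_env_fields(spec)
  grid <- fields$grid
  sst_range <- range(fields$vars$sst, na.rm = TRUE)
  if (truth$sst_optimum < sst_range[1] || truth$sst_optimum > sst_range[2])
    warning("truth SST optimum ", truth$sst_optimum,
            " outside field range [", round(sst_range[1], 1), ", ",
            round(sst_range[2], 1), "]; tracks may be degenerate")
  set.seed(substream_seed(seed, "tracks"))

  # precomputed truth logit per cell and month (-Inf on land)
  lp_arr <- truth_value(truth, fields$vars$sst, fields$vars$chl, link = "logit")
  lp_arr[is.na(lp_arr)] <- -Inf
  nlon <- length(grid$lon)
  lp_at <- function(lon, lat, month) {
    i <- floor((lon - grid$lon_range[1]) / grid$cell_size) + 1
    j <- floor((lat - grid$lat_range[1]) / grid$cell_size) + 1
    if (i < 1 || i > nlon || j < 1 || j > length(grid$lat)) return(-Inf)
    lp_arr[i, j, month]
  }

  # start animals in reasonable habitat: sample ocean cells by month-1 truth
  ocean <- which(!fields$land, arr.ind = TRUE)
  start_lp <- truth_value(truth,
                          fields$vars$sst[cbind(ocean, 1L)],
                          fields$vars$chl[cbind(ocean, 1L)], link = "logit")
  start_w <- stats::plogis(bias_strength * start_lp)  # uniform when bias = 0
  start_w[is.na(start_w)] <- 0

  years <- spec$baseline_years
  p_enter <- gap_fraction / ((1 - gap_fraction) * mean_gap_len)

  fixes <- vector("list", n_animals)
  paths <- vector("list", n_animals)
  floating_start <- stats::setNames(rep(as.Date(NA), n_animals),
                                    sprintf("A%03d", seq_len(n_animals)))
  for (a in seq_len(n_animals)) {
    id <- sprintf("A%03d", a)
    tag <- if (stats::runif(1) < psat_prob) "PSAT" else "ARGOS"
    sex <- sample(c("F", "M"), 1)
    size <- round(pmin(pmax(stats::rlnorm(1, log(6), 0.3), 2), 14), 1)
    dur <- max(30L, stats::rpois(1, mean_duration))
    start_day <- as.Date(sprintf("%d-01-01", years[1])) +
      sample.int(as.integer(365.25 * (diff(years) + 1)) - dur, 1)
    k <- sample.int(nrow(ocean), 1, prob = start_w)
    pos <- c(grid$lon[ocean[k, 1]], grid$lat[ocean[k, 2]])

    dates <- start_day + seq_len(dur) - 1L
    months <- as.integer(format(dates, "%m"))
    path <- matrix(NA_real_, dur, 2)
    for (d in seq_len(dur)) {
      for (try in 1:20) {
        ang <- stats::runif(1, 0, 2 * pi)
        len <- abs(stats::rnorm(1, 0, step_sd))
        cand <- c(pos[1] + len * cos(ang) / max(cos(pos[2] * pi / 180), 0.2),
                  pos[2] + len * sin(ang))
        cand[1] <- min(max(cand[1], grid$lon_range[1] + 1e-6),
                       grid$lon_range[2] - 1e-6)
        cand[2] <- min(max(cand[2], grid$lat_range[1] + 1e-6),
                       grid$lat_range[2] - 1e-6)
        lp <- lp_at(cand[1], cand[2], months[d])
        if (is.infinite(lp)) next                     # land: reject outright
        if (stats::runif(1) < stats::plogis(bias_strength * lp)) {
          pos <- cand
          break
        }
      }
      path[d, ] <- pos
    }

    # transmission gaps: alternate transmitting runs and geometric gaps
    transmitting <- rep(TRUE, dur)
    d <- 1L
    while (d <= dur) {
      if (stats::runif(1) < p_enter) {
        glen <- 1L + stats::rgeom(1, 1 / mean_gap_len)
        transmitting[d:min(dur, d + glen - 1L)] <- FALSE
        d <- d + glen
      }
      d <- d + 1L
    }
    transmitting[1L] <- TRUE; transmitting[dur] <- TRUE

    float <- stats::runif(1) < floating_prob
    n_track_days <- dur
    if (float) {
      fdates <- dates[dur] + seq_len(floating_days)
      dates <- c(dates, fdates)
      path <- rbind(path, cbind(path[dur, 1] + stats::rnorm(floating_days, 0, 0.004),
                                path[dur, 2] + stats::rnorm(floating_days, 0, 0.004)))
      transmitting <- c(transmitting, rep(TRUE, floating_days))
      floating_start[id] <- fdates[1]
    }

    sig <- tag_error_sigma(tag)
    keep <- which(transmitting)
    rows <- lapply(keep, function(d) {
      floating_day <- d > n_track_days
      # a detached tag floats at the surface and transmits continuously,
      # yielding many high-quality fixes per day
      nfix <- if (floating_day) sample(4:8, 1)
              else sample(1:3, 1, prob = c(0.5, 0.3, 0.2))
      err <- if (floating_day) c(lon = 0.01, lat = 0.01) else sig
      secs <- sort(stats::runif(nfix, 0, 86399))
      data.frame(
        animal_id = id,
        timestamp = as.POSIXct(as.numeric(as.POSIXct(dates[d], tz = "UTC")) +
                                 secs, tz = "UTC", origin = "1970-01-01"),
        lon = path[d, 1] + stats::rnorm(nfix, 0, err["lon"]),
        lat = path[d, 2] + stats::rnorm(nfix, 0, err["lat"]),
        tag_type = tag, sex = sex, size_m = size,
        stringsAsFactors = FALSE)
    })
    fixes[[a]] <- do.call(rbind, rows)
    paths[[a]] <- data.frame(animal_id = id, date = dates,
                             lon = path[, 1], lat = path[, 2])
  }
  out <- do.call(rbind, fixes)
  out$lat <- pmin(pmax(out$lat, -90), 90)
  attr(out, "truth_paths") <- do.call(rbind, paths)
  attr(out, "floating_start") <- floating_start
  out
}

#' Climate-ensemble specification
#'
#' @param n_models ensemble size (>= 2; the full setting uses 8 earth-system
#'   models).
#' @param per_model_bias numeric vector (recycled to `n_models`) of constant
#'   historical biases, deg C, added to each model's fields.
#' @param scenario_deltas named list `scenario -> list(variable -> end-of-century
#'   change)`; additive variables in native units, multiplicative variables as
#'   ratios.
#' @param decades named list of year ranges; defaults to 2046-2055 and
#'   2086-2095.
#' @param decade_fraction fraction of the end-of-century change realized in
#'   each decade (mid-century 0.5 by default).
#' @param noise_sd per-model field noise sd (0 makes ground-truth deltas
#'   exactly recoverable).
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_models = 8,
                          per_model_bias = seq(-1, 1, length.out = n_models),
                          scenario_deltas = list(
                            ssp126 = list(sst = 0.8, chl = 0.95),
                            ssp370 = list(sst = 2.0, chl = 0.85),
                            ssp585 = list(sst = 3.2, chl = 0.75)),
                          decades = list(`2046-2055` = c(2046, 2055),
                                         `2086-2095` = c(2086, 2095)),
                          decade_fraction = c(`2046-2055` = 0.5,
                                              `2086-2095` = 1),
                          noise_sd = 0.1) {
  stopifnot(n_models >= 2)
  per_model_bias <- rep_len(per_model_bias, n_models)
  structure(list(n_models = as.integer(n_models),
                 per_model_bias = per_model_bias,
                 scenario_deltas = scenario_deltas, decades = decades,
                 decade_fraction = decade_fraction, noise_sd = noise_sd),
            class = "ensemble_spec")
}

# Delta-change mode per variable: additive for temperature-like fields,
# multiplicative for strictly positive concentration-like fields.
#' @export
delta_mode <- function(var) {
  if (var %in% c("chl")) "multiplicative" else "additive"
}

#' Generate a synthetic multi-model climate ensemble
#'
#' Each member's historical climatology is the noise-free truth baseline plus
#' that member's constant bias plus field noise; its future climatology adds
#' the scenario trend (additive variables) or applies the scenario ratio
#' raised to the decade fraction (multiplicative variables). Ground-truth
#' deltas are exactly recoverable at `noise_sd = 0`.
#'
#' @param spec a `world_spec`.
#' @param ens an `ensemble_spec`.
#' @return object of class `climate_ensemble`: `$models[[m]]$historical` and
#'   `$models[[m]]$future[[scenario]][[decade]]`, each a named list of
#'   `[lon, lat, month]` arrays.
#' @export
gen_climate_ensemble <- function(spec, ens) {
  stopifnot(inherits(spec, "world_spec"), inherits(ens, "ensemble_spec"))
  baseline <- gen_env_fields(spec, noise_sd = list(sst = 0, chl = 0, sal = 0))
  set.seed(substream_seed(spec$seed, "ensemble"))
  vars <- intersect(unique(unlist(lapply(ens$scenario_deltas, names))),
                    names(baseline$vars))
  dm <- dim(baseline$vars[[1]])
  models <- vector("list", ens$n_models)
  for (m in seq_len(ens$n_models)) {
    hist <- list()
    for (v in vars) {
      fld <- baseline$vars[[v]]
      if (delta_mode(v) == "additive") {
        fld <- fld + ens$per_model_bias[m]
        if (ens$noise_sd > 0)
          fld <- fld + array(stats::rnorm(prod(dm), 0, ens$noise_sd), dm)
      } else {
        fld <- fld * exp(ens$per_model_bias[m] / 10)  # mild multiplicative bias
        if (ens$noise_sd > 0)
          fld <- fld * exp(array(stats::rnorm(prod(dm), 0, ens$noise_sd / 5), dm))
      }
      hist[[v]] <- fld
    }
    future <- list()
    for (sc in names(ens$scenario_deltas)) {
      future[[sc]] <- list()
      for (dec in names(ens$decades)) {
        frac <- ens$decade_fraction[[dec]]
        fl <- list()
        for (v in vars) {
          dv <- ens$scenario_deltas[[sc]][[v]]
          fl[[v]] <- if (delta_mode(v) == "additive")
            hist[[v]] + dv * frac
          else
            hist[[v]] * dv^frac
        }
        future[[sc]][[dec]] <- fl
      }
    }
    models[[m]] <- list(historical = hist, future = future)
  }
  structure(list(models = models, grid = baseline$grid,
                 months = baseline$months, land = baseline$land,
                 spec = ens, variables = vars),
            class = "climate_ensemble")
}

#' Generate a lane-structured shipping-density grid
#'
#' Annual-average vessel counts on a 0.2 degree grid over the spec domain:
#' constant low background plus `n_lanes` straight shipping lanes with
#' Gaussian cross-sections at seeded random positions and headings. Land cells
#' are NA.
#'
#' @param spec a `world_spec`.
#' @param n_lanes number of lanes (0 gives the uniform background).
#' @param background background vessel count per cell.
#' @param lane_peak peak added count at a lane axis.
#' @param lane_width lane Gaussian sd, degrees.
#' @param cell_size shipping grid resolution, degrees (default 0.2).
#' @param land_fraction western land fraction (matches [gen_env_fields()]).
#' @return object of class `shipping_grid` with `$grid` and `$counts`.
#' @export
gen_shipping <- function(spec, n_lanes = 3, background = 2, lane_peak = 400,
                         lane_width = 1, cell_size = 0.2,
                         land_fraction = 0.1) {
  stopifnot(inherits(spec, "world_spec"), n_lanes >= 0)
  grid <- make_grid(spec$lon_range, spec$lat_range, cell_size)
  set.seed(substream_seed(spec$seed, "shipping"))
  nlon <- length(grid$lon); nlat <- length(grid$lat)
  counts <- matrix(background, nlon, nlat)
  lon_m <- matrix(rep(grid$lon, times = nlat), nlon, nlat)
  lat_m <- matrix(rep(grid$lat, each = nlon), nlon, nlat)
  if (n_lanes > 0) {
    for (l in seq_len(n_lanes)) {
      theta <- stats::runif(1, 0, pi)
      x0 <- stats::runif(1, spec$lon_range[1], spec$lon_range[2])
      y0 <- stats::runif(1, spec$lat_range[1], spec$lat_range[2])
      # perpendicular distance to the lane axis through (x0, y0)
      d <- abs(-sin(theta) * (lon_m - x0) + cos(theta) * (lat_m - y0))
      counts <- counts + lane_peak * exp(-d^2 / (2 * lane_width^2))
    }
  }
  meridian <- spec$lon_range[1] + land_fraction * diff(spec$lon_range)
  counts[grid$lon < meridian, ] <- NA
  structure(list(grid = grid, counts = counts, year = 2019L),
            class = "shipping_grid")
}

#' Generate rectangular region polygons
#'
#' Non-overlapping rectangles tiling the ocean part of the domain, stand-ins
#' for exclusive economic zones / large marine ecosystems in zonal summaries.
#'
#' @param spec a `world_spec`.
#' @param n_regions number of regions (>= 1).
#' @param land_fraction western land fraction excluded from the tiling.
#' @return object of class `region_set`: data.frame with `region_id`, `name`
#'   and rectangle bounds `lon_min/lon_max/lat_min/lat_max`.
#' @export
gen_regions <- function(spec, n_regions = 6, land_fraction = 0.1) {
  stopifnot(inherits(spec, "world_spec"), n_regions >= 1)
  lon0 <- spec$lon_range[1] + land_fraction * diff(spec$lon_range)
  nr <- max(1L, floor(sqrt(n_regions)))
  nc <- ceiling(n_regions / nr)
  lon_br <- seq(lon0, spec$lon_range[2], length.out = nc + 1)
  lat_br <- seq(spec$lat_range[1], spec$lat_range[2], length.out = nr + 1)
  cells <- expand.grid(col = seq_len(nc), row = seq_len(nr))[seq_len(n_regions), ]
  out <- data.frame(
    region_id = sprintf("R%02d", seq_len(n_regions)),
    name = sprintf("Region %02d", seq_len(n_regions)),
    lon_min = lon_br[cells$col], lon_max = lon_br[cells$col + 1],
    lat_min = lat_br[cells$row], lat_max = lat_br[cells$row + 1],
    stringsAsFactors = FALSE)
  class(out) <- c("region_set", "data.frame")
  out
}

#' Write / read a region set as GeoJSON
#'
#' @param regions a `region_set`.
#' @param path file path.
#' @return `regions_to_geojson` returns `path` invisibly;
#'   `regions_from_geojson` returns a `region_set`.
#' @export
regions_to_geojson <- function(regions, path) {
  feats <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    ring <- list(c(r$lon_min, r$lat_min), c(r$lon_max, r$lat_min),
                 c(r$lon_max, r$lat_max), c(r$lon_min, r$lat_max),
                 c(r$lon_min, r$lat_min))
    list(type = "Feature",
         properties = list(region_id = r$region_id, name = r$name),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname regions_to_geojson
#' @export
regions_from_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    lons <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
    lats <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
    data.frame(region_id = f$properties$region_id, name = f$properties$name,
               lon_min = min(lons), lon_max = max(lons),
               lat_min = min(lats), lat_max = max(lats),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("region_set", "data.frame")
  out
}
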