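# Presence-background table construction: MCP-buffered background sampling,
# error-randomized environmental annotation, winsorize/centre/scale.

#' Background-sampling specification
#'
#' @param n_background_per_day candidate background points generated per
#'   presence day (default 100).
#' @param ratio background points retained per presence after subsampling
#'   (default 10, the 1:10 presence:background ratio).
#' @param lat_limit sampling crop, degrees from the equator (default 40).
#' @param seed integer seed for the sampling substreams.
#' @return object of class `sampling_spec`.
#' @export
sampling_spec <- function(n_background_per_day = 100, ratio = 10,
                          lat_limit = 40, seed = 1L) {
  stopifnot(n_background_per_day >= ratio, lat_limit > 0, lat_limit <= 90)
  structure(list(n_background_per_day = as.integer(n_background_per_day),
                 ratio = as.integer(ratio), lat_limit = lat_limit,
                 seed = as.integer(seed)),
            class = "sampling_spec")
}

#' Tag-error model for environmental annotation
#'
#' Positional uncertainty used when extracting environmental values: each
#' location is replaced by `n_randomizations` draws with per-axis normal
#' offsets of sd `inflation * sigma_axis`, truncated at `truncation * sd`,
#' where `sigma_axis` is the tag-type error radius.
#'
#' @param sigma named list per tag type of c(lon, lat) error radii in degrees.
#' @param n_randomizations draws per location (default 100).
#' @param inflation multiplier on the printed error radius (default 1.5,
#'   i.e. the radius plus half of it).
#' @param truncation truncation in sd units (default 3).
#' @return object of class `error_model`.
#' @export
error_model <- function(sigma = list(ARGOS = c(lon = 0.12, lat = 0.12),
                                     PSAT = c(lon = 0.53, lat = 1.08)),
                        n_randomizations = 100, inflation = 1.5,
                        truncation = 3) {
  stopifnot(n_randomizations >= 1, all(unlist(sigma) >= 0))
  structure(list(sigma = sigma,
                 n_randomizations = as.integer(n_randomizations),
                 inflation = inflation, truncation = truncation),
            class = "error_model")
}

#' Minimum convex polygon of presence locations
#'
#' @param lon,lat presence coordinates (>= 3 non-collinear points).
#' @return closed polygon matrix (columns lon, lat; first vertex repeated
#'   last), class `mcp_polygon`.
#' @export
compute_mcp <- function(lon, lat) {
  pts <- unique(cbind(lon, lat))
  if (nrow(pts) < 3) stop("need at least 3 distinct points for an MCP")
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3) stop("presence points are collinear; MCP degenerate")
  poly <- pts[c(h, h[1]), , drop = FALSE]
  colnames(poly) <- c("lon", "lat")
  class(poly) <- c("mcp_polygon", class(poly))
  poly
}

#' Shoelace area of a closed polygon (degrees^2)
#' @param poly closed polygon matrix (first vertex == last).
#' @return signed-area magnitude.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Point-in-polygon test
#' @param poly closed polygon matrix.
#' @param lon,lat query coordinates.
#' @return logical vector.
#' @export
point_in_mcp <- function(poly, lon, lat) {
  mgcv::in.out(unclass(poly), cbind(lon, lat))
}

#' Sample background locations outside the MCP buffer
#'
#' For each presence day draws `n_background_per_day` points over the ocean
#' cells of the basin extent (cells sampled proportional to spherical area,
#' uniform position within the cell), rejecting points inside the MCP or
#' poleward of `lat_limit`. Each background inherits its presence day's date
#' and animal metadata for temporal annotation.
#'
#' @param daily daily presence track table (rows = presence days).
#' @param fields `env_fields` supplying the ocean mask and basin grid.
#' @param mcp polygon from [compute_mcp()].
#' @param spec a `sampling_spec`.
#' @return data.frame of background points with `presence_row` linking each to
#'   its presence day.
#' @export
sample_background <- function(daily, fields, mcp, spec) {
  stopifnot(inherits(spec, "sampling_spec"))
  grid <- fields$grid
  lat_ok <- abs(grid$lat) <= spec$lat_limit
  ocean <- !fields$land & matrix(rep(lat_ok, each = length(grid$lon)),
                                 length(grid$lon), length(grid$lat))
  cand <- which(ocean)
  if (length(cand) == 0) stop("no sampleable ocean cells within lat limit")
  areas <- cell_areas(grid)
  w <- areas[cand]
  nlon <- length(grid$lon)
  set.seed(substream_seed(spec$seed, "background"))
  n_need <- spec$n_background_per_day
  out <- vector("list", nrow(daily))
  for (r in seq_len(nrow(daily))) {
    got <- matrix(numeric(0), 0, 2)
    while (nrow(got) < n_need) {
      m <- 2L * (n_need - nrow(got)) + 20L
      k <- sample.int(length(cand), m, replace = TRUE, prob = w)
      ci <- (cand[k] - 1L) %% nlon + 1L
      cj <- (cand[k] - 1L) %/% nlon + 1L
      x <- grid$lon[ci] + stats::runif(m, -0.5, 0.5) * grid$cell_size
      y <- grid$lat[cj] + stats::runif(m, -0.5, 0.5) * grid$cell_size
      keep <- abs(y) <= spec$lat_limit & !point_in_mcp(mcp, x, y)
      got <- rbind(got, cbind(x[keep], y[keep]))
      if (nrow(got) == 0 && m > 10000)
        stop("no sampleable area: basin fully covered by the MCP buffer")
    }
    got <- got[seq_len(n_need), , drop = FALSE]
    out[[r]] <- data.frame(presence_row = r, lon = got[, 1], lat = got[, 2])
  }
  bg <- do.call(rbind, out)
  meta <- daily[bg$presence_row,
                intersect(c("date", "animal_id", "tag_type", "sex", "size_m"),
                          names(daily)), drop = FALSE]
  rownames(meta) <- NULL
  cbind(bg, meta)
}

#' Subsample backgrounds to the presence:background ratio
#'
#' Uniform seeded subsample keeping exactly `spec$ratio` background points per
#' presence day.
#'
#' @param backgrounds output of [sample_background()].
#' @param spec a `sampling_spec`.
#' @return subsampled background data.frame.
#' @export
subsample_ratio <- function(backgrounds, spec) {
  set.seed(substream_seed(spec$seed, "subsample"))
  parts <- split(seq_len(nrow(backgrounds)), backgrounds$presence_row)
  short <- vapply(parts, length, 0L) < spec$ratio
  if (any(short))
    stop("insufficient backgrounds: need >= ", spec$ratio, " per presence")
  keep <- unlist(lapply(parts, function(ix) sample(ix, spec$ratio)))
  out <- backgrounds[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Cells of a [lon, lat, month] array whose centres fall in the res-wide window
# around (x, y), enumerated in outward spiral order (centre cell first, then
# rings by increasing Chebyshev radius, each ring counter-clockwise from
# east). The mean is order-independent; the spiral order exists so extraction
# can stop early when enough non-missing cells are seen.
#' @export
#' @rdname annotate_env
spiral_window_values <- function(values, grid, x, y, res) {
  half <- res / 2
  ci <- cell_index(grid, x, y)
  ii <- which(abs(grid$lon - x) <= half)
  jj <- which(abs(grid$lat - y) <= half)
  if (length(ii) == 0 || length(jj) == 0) return(numeric(0))
  cells <- expand.grid(i = ii, j = jj)
  di <- cells$i - ci$i[1]; dj <- cells$j - ci$j[1]
  ring <- pmax(abs(di), abs(dj))
  ang <- atan2(dj, di) %% (2 * pi)
  ord <- order(ring, ang)
  values[cbind(cells$i[ord], cells$j[ord])]
}

# Plain mean over the res-wide window centred on (x, y); NA cells skipped.
window_mean <- function(values, grid, x, y, res) {
  half <- res / 2
  ii <- which(abs(grid$lon - x) <= half)
  jj <- which(abs(grid$lat - y) <= half)
  if (length(ii) == 0 || length(jj) == 0) return(NA_real_)
  v <- values[ii, jj]
  if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

# Fractional month position of a date against mid-month climatology stamps.
# Returns (m1, m2, w): value = (1-w)*field[m1] + w*field[m2].
month_interp_weights <- function(dates) {
  mids <- cumsum(c(0, 31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30)) +
    c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31) / 2   # day-of-year mid-month
  doy <- as.integer(strftime(dates, "%j"))
  doy <- pmin(doy, 365)
  m1 <- m2 <- integer(length(doy)); w <- numeric(length(doy))
  for (k in seq_along(doy)) {
    d <- doy[k]
    if (d < mids[1]) {          # wrap Dec -> Jan
      m1[k] <- 12L; m2[k] <- 1L
      w[k] <- (d + 365 - mids[12]) / (mids[1] + 365 - mids[12])
    } else if (d >= mids[12]) {
      m1[k] <- 12L; m2[k] <- 1L
      w[k] <- (d - mids[12]) / (mids[1] + 365 - mids[12])
    } else {
      m1[k] <- findInterval(d, mids)
      m2[k] <- m1[k] + 1L
      w[k] <- (d - mids[m1[k]]) / (mids[m2[k]] - mids[m1[k]])
    }
  }
  data.frame(m1 = m1, m2 = m2, w = w)
}

#' Error-randomized environmental annotation
#'
#' For each point, draws `n_randomizations` error-offset locations from the
#' tag's error model, averages the native-grid cells inside the
#' `analysis_resolution` window centred on each draw (missing cells skipped),
#' then averages the draws. Monthly variables are interpolated linearly in
#' time between the two nearest mid-month climatology stamps; static
#' variables (e.g. bathymetry) skip the temporal step.
#'
#' @param points data.frame with `lon`, `lat`, `date` and `tag_type`
#'   (tag type may be absent when `em` has `sigma = 0`, e.g. background
#'   points, which are annotated without positional error).
#' @param fields an `env_fields`.
#' @param em an `error_model`, or NULL for exact-location extraction.
#' @param analysis_resolution averaging window width, degrees (default 0.25).
#' @param vars variables to annotate (default all dynamic + static).
#' @param seed seed for the offset draws.
#' @return data.frame of covariate columns aligned with `points` rows (NA
#'   where every window cell was missing).
#' @export
annotate_env <- function(points, fields, em = NULL,
                         analysis_resolution = 0.25, vars = NULL, seed = 1L) {
  n <- nrow(points)
  if (is.null(vars)) vars <- c(names(fields$vars), names(fields$static))
  grid <- fields$grid
  res <- analysis_resolution

  # error-offset draws per point: matrix n x n_rand per axis
  if (is.null(em)) {
    nr <- 1L
    lon_d <- matrix(points$lon, n, 1)
    lat_d <- matrix(points$lat, n, 1)
  } else {
    nr <- em$n_randomizations
    set.seed(substream_seed(seed, "annotate"))
    sig <- t(vapply(as.character(points$tag_type),
                    function(tt) em$sigma[[tt]], c(lon = 0, lat = 0)))
    draw <- function(sd_axis) {
      z <- matrix(stats::rnorm(n * nr), n, nr)
      z <- pmin(pmax(z, -em$truncation), em$truncation)
      z * (em$inflation * sd_axis)
    }
    lon_d <- points$lon + draw(sig[, "lon"])
    lat_d <- points$lat + draw(sig[, "lat"])
  }

  # window means, vectorized: window spans at most 2 cells per axis when the
  # native grid matches the analysis resolution; enumerate the (up to 4 x
  # n-native-per-window) candidate cells via index offsets.
  half <- res / 2
  kmax <- ceiling(half / grid$cell_size - 1e-9)
  offs <- -kmax:kmax
  win_mean_vec <- function(values, x, y) {
    ix0 <- cell_index(grid, x, y)
    acc <- num <- rep(0, length(x))
    for (di in offs) for (dj in offs) {
      i <- ix0$i + di; j <- ix0$j + dj
      ok <- !is.na(i) & !is.na(j) & i >= 1 & i <= length(grid$lon) &
        j >= 1 & j <= length(grid$lat)
      ok[ok] <- abs(grid$lon[i[ok]] - x[ok]) <= half &
        abs(grid$lat[j[ok]] - y[ok]) <= half
      v <- rep(NA_real_, length(x))
      v[ok] <- values[cbind(i[ok], j[ok])]
      use <- !is.na(v)
      acc[use] <- acc[use] + v[use]
      num[use] <- num[use] + 1
    }
    ifelse(num > 0, acc / num, NA_real_)
  }

  tw <- month_interp_weights(points$date)
  out <- list()
  for (v in vars) {
    static <- v %in% names(fields$static)
    per_draw <- matrix(NA_real_, n, nr)
    for (r in seq_len(nr)) {
      x <- lon_d[, r]; y <- lat_d[, r]
      if (static) {
        per_draw[, r] <- win_mean_vec(fields$static[[v]], x, y)
      } else {
        arr <- fields$vars[[v]]
        v1 <- v2 <- rep(NA_real_, n)
        for (m in sort(unique(c(tw$m1, tw$m2)))) {
          sl <- arr[, , m]
          need1 <- tw$m1 == m; need2 <- tw$m2 == m
          if (any(need1)) v1[need1] <- win_mean_vec(sl, x[need1], y[need1])
          if (any(need2)) v2[need2] <- win_mean_vec(sl, x[need2], y[need2])
        }
        per_draw[, r] <- (1 - tw$w) * v1 + tw$w * v2
      }
    }
    out[[v]] <- rowMeans(per_draw, na.rm = TRUE)
    out[[v]][is.nan(out[[v]])] <- NA_real_
  }
  as.data.frame(out)
}

#' Winsorize, centre and scale covariates per region
#'
#' Clips each covariate to its (p_low, p_high) percentiles, then centres and
#' scales it, independently within each region. The scaling record is stored
#' so prediction grids are transformed identically at prediction time.
#'
#' @param table PBTable data.frame with a `region` column.
#' @param covariates covariate column names.
#' @param limits clipping percentiles (default c(1, 99)).
#' @return list with the transformed `table` and the `scaling` record
#'   (region -> covariate -> lo/hi/mean/sd).
#' @export
winsorize_and_scale <- function(table, covariates, limits = c(1, 99)) {
  if (is.null(table$region)) table$region <- "all"
  scaling <- list()
  for (reg in unique(table$region)) {
    rows <- table$region == reg
    scaling[[reg]] <- list()
    for (cv in covariates) {
      x <- table[[cv]][rows]
      qs <- stats::quantile(x, limits / 100, na.rm = TRUE, names = FALSE,
                            type = 7)
      x <- pmin(pmax(x, qs[1]), qs[2])
      mu <- mean(x, na.rm = TRUE); sdv <- stats::sd(x, na.rm = TRUE)
      if (!is.finite(sdv) || sdv == 0)
        stop("zero-variance covariate after winsorizing: ", cv,
             " (region ", reg, ")")
      table[[cv]][rows] <- (x - mu) / sdv
      scaling[[reg]][[cv]] <- list(lo = qs[1], hi = qs[2], mean = mu, sd = sdv)
    }
  }
  list(table = table, scaling = scaling)
}

#' Apply a stored scaling record to new covariate values
#'
#' @param x numeric vector of raw covariate values.
#' @param scaling scaling record from [winsorize_and_scale()].
#' @param region region key.
#' @param covariate covariate name.
#' @param invert back-transform scaled values to raw units (no un-clipping).
#' @return transformed numeric vector.
#' @export
apply_scaling <- function(x, scaling, region, covariate, invert = FALSE) {
  s <- scaling[[region]][[covariate]]
  if (is.null(s)) stop("no scaling record for ", covariate, " in ", region)
  if (invert) return(x * s$sd + s$mean)
  (pmin(pmax(x, s$lo), s$hi) - s$mean) / s$sd
}

#' Build the presence-background model table
#'
#' End-to-end construction: MCP from all presence days, per-day background
#' sampling, 1:10 subsampling, error-randomized annotation of presences and
#' exact-location annotation of backgrounds, winsorize/centre/scale. Rows
#' whose covariates are all-missing at annotation are dropped (count logged).
#'
#' @param daily daily presence track (thinned for modelling).
#' @param fields an `env_fields`.
#' @param sspec a `sampling_spec`.
#' @param em an `error_model` applied to presence annotation.
#' @param region region label stored on every row.
#' @param limits winsorizing percentiles.
#' @return list: `table` (PBTable), `scaling`, `mcp`, `n_dropped`.
#' @export
build_pb_table <- function(daily, fields, sspec = sampling_spec(),
                           em = error_model(), region = "all",
                           limits = c(1, 99)) {
  mcp <- compute_mcp(daily$lon, daily$lat)
  bg <- sample_background(daily, fields, mcp, sspec)
  bg <- subsample_ratio(bg, sspec)

  covs <- c(names(fields$vars), names(fields$static))
  pres_cov <- annotate_env(daily, fields, em, seed = sspec$seed)
  bg_cov <- annotate_env(bg, fields, em = NULL, seed = sspec$seed)

  mk <- function(pts, cov, label, presence_row) {
    data.frame(label = label, presence_row = presence_row,
               animal_id = pts$animal_id, date = pts$date,
               month = as.integer(format(pts$date, "%m")),
               lon = pts$lon, lat = pts$lat,
               sex = if (!is.null(pts$sex)) pts$sex else NA_character_,
               size_m = if (!is.null(pts$size_m)) pts$size_m else NA_real_,
               region = region, cov, stringsAsFactors = FALSE)
  }
  tab <- rbind(mk(daily, pres_cov, 1L, seq_len(nrow(daily))),
               mk(bg, bg_cov, 0L, bg$presence_row))
  # keep whole presence-day groups only, preserving the exact 1:ratio pairing
  complete <- stats::complete.cases(tab[covs])
  bad_groups <- unique(tab$presence_row[!complete])
  n_dropped <- sum(tab$presence_row %in% bad_groups)
  tab <- tab[!(tab$presence_row %in% bad_groups), , drop = FALSE]
  if (nrow(tab) == 0) stop("all rows dropped during annotation")
  tab$presence_row <- NULL
  rownames(tab) <- NULL
  ws <- winsorize_and_scale(tab, covs, limits)
  list(table = ws$table, scaling = ws$scaling, mcp = mcp,
       n_dropped = n_dropped, covariates = covs)
}
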