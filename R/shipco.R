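# Ship co-occurrence index (SCI): per-cell product of habitat suitability and
# normalized shipping density, averaged within regions, with percent change
# from the baseline period. Shipping is held fixed at the baseline-year grid
# across all scenarios.

#' Conservative regrid of a shipping grid onto the analysis grid
#'
#' Overlap-area-weighted mean of source cells per target cell, with exact
#' spherical weights (longitude overlap times sine-latitude band overlap), so
#' total vessel mass is conserved wherever the target tiles the valid source.
#'
#' @param ship a `shipping_grid`.
#' @param target a `ps_grid` (the 0.25 degree analysis grid).
#' @return `[lon, lat]` matrix of mean counts on `target` (NA where no valid
#'   source cell overlaps).
#' @export
regrid_shipping <- function(ship, target) {
  src <- ship$grid
  if (max(src$lon_range[1], target$lon_range[1]) >=
      min(src$lon_range[2], target$lon_range[2]) ||
      max(src$lat_range[1], target$lat_range[1]) >=
      min(src$lat_range[2], target$lat_range[2]))
    stop("shipping and target grids do not overlap")
  edges <- function(centres, cs) cbind(centres - cs / 2, centres + cs / 2)
  ovl <- function(a, b) {  # pairwise 1-D interval overlap lengths
    lo <- outer(a[, 1], b[, 1], pmax)
    hi <- outer(a[, 2], b[, 2], pmin)
    pmax(hi - lo, 0)
  }
  et_lon <- edges(target$lon, target$cell_size)
  es_lon <- edges(src$lon, src$cell_size)
  A <- ovl(et_lon, es_lon)                         # [n_t_lon, n_s_lon], degrees
  sin_ovl <- function(a, b) {                      # sine-band overlap
    lo <- outer(a[, 1], b[, 1], pmax) * pi / 180
    hi <- outer(a[, 2], b[, 2], pmin) * pi / 180
    out <- sin(hi) - sin(lo)
    out[out < 0] <- 0
    out
  }
  B <- sin_ovl(edges(target$lat, target$cell_size),
               edges(src$lat, src$cell_size))      # [n_t_lat, n_s_lat]
  V <- ship$counts
  M <- ifelse(is.na(V), 0, 1)
  V0 <- ifelse(is.na(V), 0, V)
  num <- A %*% V0 %*% t(B)
  den <- A %*% M %*% t(B)
  out <- num / den
  out[den <= 0] <- NA_real_
  out
}

#' Ship co-occurrence index map
#'
#' `SCI = suitability x shipping / norm`, where `norm` is the maximum shipping
#' count over ocean cells of the baseline grid — computed once and reused for
#' every period so baseline and projected maps share a scale.
#'
#' @param suitability a `suitability_map`.
#' @param shipping shipping counts on the same grid (from
#'   [regrid_shipping()]).
#' @param norm normalization constant; NULL (default) uses
#'   `max(shipping, na.rm = TRUE)` (compute it once from the baseline grid
#'   and pass it to every period).
#' @param transform "linear" scales raw counts by `norm`;
#'   "log1p" uses `log1p(counts) / log1p(norm)`, compressing the heavy tail
#'   of vessel densities so off-lane traffic is not rounded to zero.
#' @return object of class `sci_map` with `$values`, `$norm`, `$transform`.
#' @export
sci_map <- function(suitability, shipping, norm = NULL,
                    transform = c("linear", "log1p")) {
  transform <- match.arg(transform)
  stopifnot(identical(dim(suitability$values), dim(shipping)))
  if (all(is.na(shipping)) || max(shipping, na.rm = TRUE) <= 0)
    stop("all-zero shipping grid")
  if (is.null(norm)) norm <- max(shipping, na.rm = TRUE)
  ship_scaled <- if (transform == "linear") shipping / norm
                 else log1p(shipping) / log1p(norm)
  vals <- suitability$values * ship_scaled
  structure(list(grid = suitability$grid, values = vals, norm = norm,
                 transform = transform, label = suitability$label),
            class = "sci_map")
}

#' Mean SCI within each region
#'
#' Unweighted mean over the region's ocean cells (cell-centre membership).
#'
#' @param sci an `sci_map`.
#' @param regions a `region_set`.
#' @return named numeric vector of means (NA for regions with no ocean cells).
#' @export
sci_region_means <- function(sci, regions) {
  out <- vapply(seq_len(nrow(regions)), function(k) {
    inreg <- region_mask(sci$grid, regions[k, ]) & !is.na(sci$values)
    if (!any(inreg)) NA_real_ else mean(sci$values[inreg])
  }, 0)
  stats::setNames(out, regions$region_id)
}

#' Per-region SCI change and aggregates
#'
#' Percent change from baseline per region; regions with mean SCI below
#' `floor` in both periods are excluded from the aggregates (they remain in
#' the listing with `included = FALSE`). Two aggregate framings are reported:
#' (i) the mean of per-region fold changes (future/baseline) over included
#' regions with finite fold change, and (ii) the percent change of the
#' across-region mean SCI — the normalization constant cancels in (ii).
#'
#' @param baseline_means,future_means named vectors from
#'   [sci_region_means()] over the same regions.
#' @param floor exclusion threshold (default 0.1).
#' @return list: `table` (region_id, baseline, future, pct_change,
#'   fold_change, included), `mean_fold_change`, `pct_change_of_mean`.
#' @export
sci_change <- function(baseline_means, future_means, floor = 0.1) {
  stopifnot(identical(names(baseline_means), names(future_means)))
  b <- baseline_means; f <- future_means
  pct <- ifelse(b > 0, (f - b) / b * 100, ifelse(f > 0, Inf, 0))
  fold <- ifelse(b > 0, f / b, ifelse(f > 0, Inf, NA_real_))
  included <- !(b < floor & f < floor)
  included[is.na(b) | is.na(f)] <- FALSE
  tab <- data.frame(region_id = names(b), baseline = unname(b),
                    future = unname(f), pct_change = unname(pct),
                    fold_change = unname(fold), included = unname(included),
                    stringsAsFactors = FALSE)
  use_i <- included & is.finite(fold)
  mean_fold <- if (any(use_i)) mean(fold[use_i]) else NA_real_
  use_ii <- included
  pct_of_mean <- if (any(use_ii))
    (mean(f[use_ii]) - mean(b[use_ii])) / mean(b[use_ii]) * 100
  else NA_real_
  list(table = tab, mean_fold_change = mean_fold,
       pct_change_of_mean = pct_of_mean,
       n_included = sum(included))
}
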