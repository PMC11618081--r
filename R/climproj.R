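# Delta-change climate projection: per-model change fields, ensemble
# averaging, application to the baseline climatology. Model bias cancels by
# construction: a constant offset added to one member's historical AND future
# fields leaves its additive delta unchanged.

#' Scenario/decade key
#'
#' @param scenario one of "ssp126", "ssp370", "ssp585".
#' @param decade one of "2046-2055", "2086-2095".
#' @return object of class `scenario_key`.
#' @export
scenario_key <- function(scenario, decade) {
  scenario <- match.arg(scenario, c("ssp126", "ssp370", "ssp585"))
  decade <- match.arg(decade, c("2046-2055", "2086-2095"))
  structure(list(scenario = scenario, decade = decade), class = "scenario_key")
}

#' All six scenario x decade combinations
#' @return list of `scenario_key` objects.
#' @export
all_scenario_keys <- function() {
  out <- list()
  for (sc in c("ssp126", "ssp370", "ssp585"))
    for (dec in c("2046-2055", "2086-2095"))
      out[[paste(sc, dec, sep = "_")]] <- scenario_key(sc, dec)
  out
}

#' Per-model delta field
#'
#' Additive: `future - historical`. Multiplicative: `future / historical`,
#' with historical cells below `eps` masked.
#'
#' @param model_hist,model_future arrays/matrices on a common grid (regrid
#'   first with [regrid_bilinear()] if needed).
#' @param mode "additive" or "multiplicative".
#' @param eps divide-by-zero guard for multiplicative deltas (default 1e-6).
#' @return delta array of the same shape.
#' @export
compute_delta <- function(model_hist, model_future,
                          mode = c("additive", "multiplicative"),
                          eps = 1e-6) {
  mode <- match.arg(mode)
  if (!identical(dim(model_hist), dim(model_future)))
    stop("grid mismatch between historical and future fields")
  if (mode == "additive") {
    model_future - model_hist
  } else {
    out <- model_future / model_hist
    out[abs(model_hist) < eps] <- NA_real_
    out
  }
}

#' Ensemble-mean delta field
#'
#' Cellwise arithmetic mean of additive member deltas, geometric mean of
#' multiplicative ones.
#'
#' @param deltas list of per-model delta arrays (common shape and mode).
#' @param mode "additive" or "multiplicative".
#' @param variable variable name recorded on the result.
#' @param key optional `scenario_key` recorded on the result.
#' @return object of class `delta_field` with `$values`, `$mode`,
#'   `$n_models`.
#' @export
ensemble_delta <- function(deltas, mode = c("additive", "multiplicative"),
                           variable = "", key = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(deltas) >= 1)
  dm <- dim(deltas[[1]])
  if (!all(vapply(deltas, function(d) identical(dim(d), dm), TRUE)))
    stop("member deltas on different grids")
  if (mode == "multiplicative" && any(unlist(deltas) < 0, na.rm = TRUE))
    stop("negative multiplicative delta")
  vals <- if (length(deltas) == 1) {
    deltas[[1]]                    # identity; keeps single-member case exact
  } else if (mode == "additive") {
    apply(simplify2array(deltas), seq_along(dm), mean)
  } else {
    exp(apply(log(simplify2array(deltas)), seq_along(dm), mean))
  }
  structure(list(variable = variable, values = vals, mode = mode,
                 key = key, n_models = length(deltas)),
            class = "delta_field")
}

#' Apply a delta field to a baseline climatology
#'
#' Additive deltas are added, multiplicative deltas multiplied; the result is
#' clamped to the variable's physical range (chlorophyll and salinity >= 0).
#' Missing in either input stays missing.
#'
#' @param baseline baseline array/matrix for one variable.
#' @param delta a `delta_field` (or bare array) on the same grid.
#' @param variable variable name (controls clamping); taken from the
#'   `delta_field` when omitted.
#' @return projected array of the same shape.
#' @export
apply_delta <- function(baseline, delta, variable = NULL) {
  if (inherits(delta, "delta_field")) {
    if (is.null(variable)) variable <- delta$variable
    mode <- delta$mode
    delta <- delta$values
  } else {
    mode <- delta_mode(variable)
  }
  if (!identical(dim(baseline), dim(delta)))
    stop("grid mismatch between baseline and delta")
  out <- if (mode == "additive") baseline + delta else baseline * delta
  if (!is.null(variable) && variable %in% c("chl", "sal"))
    out <- pmax(out, 0)
  out
}

#' Project baseline fields to a scenario and decade
#'
#' For each ensemble variable: per-model deltas (additive or multiplicative by
#' [delta_mode()]), ensemble mean, regrid to the baseline grid if the ensemble
#' is coarser, and application to the baseline monthly climatology. Variables
#' the ensemble does not cover are carried through unchanged.
#'
#' @param fields baseline `env_fields`.
#' @param ensemble a `climate_ensemble`.
#' @param key a `scenario_key`.
#' @return projected `env_fields` with the scenario label in `$meta$period`.
#' @export
project_fields <- function(fields, ensemble, key) {
  stopifnot(inherits(key, "scenario_key"))
  out <- fields
  same_grid <- identical(ensemble$grid$lon, fields$grid$lon) &&
    identical(ensemble$grid$lat, fields$grid$lat)
  for (v in ensemble$variables) {
    mode <- delta_mode(v)
    deltas <- lapply(ensemble$models, function(m)
      compute_delta(m$historical[[v]], m$future[[key$scenario]][[key$decade]][[v]],
                    mode))
    ed <- ensemble_delta(deltas, mode, variable = v, key = key)
    vals <- ed$values
    if (!same_grid) {
      nm <- dim(vals)[3]
      regr <- array(NA_real_, c(length(fields$grid$lon),
                                length(fields$grid$lat), nm))
      for (m in seq_len(nm))
        regr[, , m] <- regrid_bilinear(vals[, , m], ensemble$grid, fields$grid)
      vals <- regr
    }
    ed$values <- vals
    out$vars[[v]] <- apply_delta(fields$vars[[v]], ed, variable = v)
  }
  out$meta$period <- paste(key$scenario, key$decade, sep = "_")
  out
}
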