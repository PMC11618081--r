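# Presence-background additive habitat models: collinearity screening,
# penalized binomial GAMs (mgcv) with cyclic month smooths and random
# intercepts, wAIC hypothesis comparison, pruning, cross-validated skill
# metrics, continuous Boyce index, suitability / favourability surfaces.

#' Model hypothesis specification
#'
#' @param name label for the hypothesis.
#' @param covariates environmental covariate names (columns of the PBTable).
#' @param k smooth basis size per covariate; kept low to avoid overfitting
#'   (default 5, must be <= 6).
#' @param include_month add a cyclic cubic spline of month (period 12).
#' @param random_effects subset of c("animal_id", "sex", "size_class") fitted
#'   as random intercepts.
#' @return object of class `hypothesis_spec`.
#' @export
hypothesis_spec <- function(name, covariates, k = 5, include_month = TRUE,
                            random_effects = c("animal_id", "sex",
                                               "size_class")) {
  stopifnot(length(covariates) >= 1, k >= 3, k <= 6)
  structure(list(name = name, covariates = covariates, k = as.integer(k),
                 include_month = include_month,
                 random_effects = random_effects),
            class = "hypothesis_spec")
}

#' Greedy collinearity screen
#'
#' Repeatedly finds the covariate pair with the largest |Pearson r| at or
#' above `threshold` and drops the member with the higher mean absolute
#' correlation to all other covariates.
#'
#' @param table PBTable.
#' @param covariates candidate covariate names (>= 2).
#' @param threshold |r| cutoff (default 0.7).
#' @return retained covariate names.
#' @export
screen_collinearity <- function(table, covariates, threshold = 0.7) {
  stopifnot(length(covariates) >= 2)
  keep <- covariates
  repeat {
    if (length(keep) < 2) break
    cm <- abs(stats::cor(table[keep], use = "pairwise.complete.obs"))
    diag(cm) <- 0
    if (max(cm, na.rm = TRUE) < threshold) break
    ij <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1, ]
    pair <- keep[ij]
    drop <- pair[which.max(colMeans(cm[, pair, drop = FALSE]))]
    keep <- setdiff(keep, drop)
  }
  keep
}

# factor prep shared by fitting and prediction
prep_model_frame <- function(table, size_breaks = c(0, 4, 8, Inf)) {
  table$animal_id <- factor(table$animal_id)
  table$sex <- factor(ifelse(is.na(table$sex), "U", table$sex))
  table$size_class <- cut(ifelse(is.na(table$size_m), 0, table$size_m),
                          breaks = size_breaks,
                          labels = c("small", "medium", "large"),
                          include.lowest = TRUE)
  table
}

build_formula <- function(hyp) {
  terms <- sprintf("s(%s, k = %d)", hyp$covariates, hyp$k)
  if (hyp$include_month)
    terms <- c(terms, "s(month, bs = \"cc\", k = 6)")
  for (re in hyp$random_effects)
    terms <- c(terms, sprintf("s(%s, bs = \"re\")", re))
  stats::as.formula(paste("label ~", paste(terms, collapse = " + ")))
}

#' Fit a binomial additive habitat model
#'
#' Binomial (logit) GAM over the presence-background table: penalized thin
#' plate smooths per covariate with the smoothness penalty inflated by
#' `gamma = 1.4` against overfitting, a cyclic cubic spline of month, and
#' random intercepts for animal identity / sex / size class. Uses
#' `mgcv::bam` (fast ML, discretized covariates) above `bam_threshold` rows,
#' `mgcv::gam` (REML) otherwise.
#'
#' @param table PBTable (scaled covariates).
#' @param hyp a `hypothesis_spec`.
#' @param gamma smoothness-penalty inflation (default 1.4).
#' @param min_presences fitting floor on presence rows (default 50).
#' @param bam_threshold row count above which `bam` is used (default 5000).
#' @return object of class `hab_model`: the mgcv fit plus hypothesis, AIC,
#'   percent deviance explained, per-term p-values and training prevalence.
#' @export
fit_hab_model <- function(table, hyp, gamma = 1.4, min_presences = 50,
                          bam_threshold = 5000) {
  stopifnot(inherits(hyp, "hypothesis_spec"))
  missing_cov <- setdiff(hyp$covariates, names(table))
  if (length(missing_cov))
    stop("covariates absent from table: ", paste(missing_cov, collapse = ", "))
  n1 <- sum(table$label == 1)
  if (n1 < min_presences)
    stop("need at least ", min_presences, " presences; got ", n1)
  df <- prep_model_frame(table)
  # random-effect factors need >= 2 observed levels to be estimable
  ok_re <- vapply(hyp$random_effects,
                  function(re) length(unique(df[[re]])) >= 2, TRUE)
  if (!all(ok_re)) {
    hyp$random_effects <- hyp$random_effects[ok_re]
  }
  form <- build_formula(hyp)
  knots <- if (hyp$include_month) list(month = c(0.5, 12.5)) else NULL
  fit <- if (nrow(df) > bam_threshold) {
    mgcv::bam(form, data = df, family = stats::binomial(), gamma = gamma,
              method = "fREML", discrete = TRUE, knots = knots)
  } else {
    mgcv::gam(form, data = df, family = stats::binomial(), gamma = gamma,
              method = "REML", knots = knots)
  }
  if (!fit$converged) stop("model did not converge for hypothesis ", hyp$name)
  sm <- summary(fit)
  structure(list(fit = fit, hyp = hyp, gamma = gamma,
                 aic = stats::AIC(fit),
                 dev_expl = 100 * sm$dev.expl,
                 pvalues = sm$s.table[, "p-value"],
                 prevalence = n1 / nrow(df),
                 n_rows = nrow(df),
                 size_levels = levels(df$size_class),
                 id_levels = levels(df$animal_id),
                 sex_levels = levels(df$sex)),
            class = "hab_model")
}

#' @export
print.hab_model <- function(x, ...) {
  cat(sprintf("<hab_model> '%s': AIC %.1f, deviance explained %.1f%%, prevalence %.3f\n",
              x$hyp$name, x$aic, x$dev_expl, x$prevalence))
  invisible(x)
}

#' Drop non-significant environmental terms and refit once
#'
#' Removes covariate smooths with approximate p > `alpha` (month and random
#' effects are retained as model structure) and refits the reduced model.
#'
#' @param model a `hab_model`.
#' @param table the fitting PBTable.
#' @param alpha significance cutoff (default 0.05).
#' @return refitted `hab_model` (identical hypothesis if nothing is dropped).
#' @export
prune_nonsignificant <- function(model, table, alpha = 0.05) {
  pv <- model$pvalues
  env_terms <- sprintf("s(%s)", model$hyp$covariates)
  pv_env <- pv[names(pv) %in% env_terms]
  drop <- names(pv_env)[pv_env > alpha]
  if (length(drop) == 0) return(model)
  keep <- model$hyp$covariates[!(env_terms %in% drop)]
  if (length(keep) == 0) stop("all environmental terms non-significant")
  hyp2 <- hypothesis_spec(paste0(model$hyp$name, "_pruned"), keep,
                          k = model$hyp$k,
                          include_month = model$hyp$include_month,
                          random_effects = model$hyp$random_effects)
  fit_hab_model(table, hyp2, gamma = model$gamma)
}

#' Akaike weights across a candidate model set
#'
#' `w_i = exp(-d_i / 2) / sum_j exp(-d_j / 2)` with `d_i = AIC_i - min AIC`.
#' Models must be fitted to the same rows.
#'
#' @param models list of `hab_model` objects (>= 2).
#' @return named numeric vector of weights summing to 1.
#' @export
compare_waic <- function(models) {
  stopifnot(length(models) >= 2)
  n <- vapply(models, function(m) m$n_rows, 0)
  if (length(unique(n)) != 1)
    stop("models were fitted to different numbers of rows")
  aic <- vapply(models, function(m) m$aic, 0)
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w <- w / sum(w)
  names(w) <- vapply(models, function(m) m$hyp$name, "")
  w
}

#' Partial response of one covariate
#'
#' Smooth-term contribution over the covariate's observed range, other terms
#' held at zero; the x axis is returned in raw units via the scaling record.
#'
#' @param model a `hab_model`.
#' @param covariate covariate name.
#' @param scaling,region scaling record and region key to unscale the axis
#'   (NULL leaves scaled units).
#' @param n evaluation points.
#' @return data.frame with `x` (covariate value) and `effect` (logit scale).
#' @export
partial_response <- function(model, covariate, scaling = NULL,
                             region = "all", n = 200) {
  fit <- model$fit
  mf <- fit$model
  xr <- range(mf[[covariate]], na.rm = TRUE)
  nd <- mf[rep(1, n), , drop = FALSE]
  nd[[covariate]] <- seq(xr[1], xr[2], length.out = n)
  tm <- stats::predict(fit, nd, type = "terms")
  eff <- tm[, paste0("s(", covariate, ")")]
  x <- nd[[covariate]]
  if (!is.null(scaling))
    x <- apply_scaling(x, scaling, region, covariate, invert = TRUE)
  data.frame(x = x, effect = as.numeric(eff))
}

#' Predict a habitat-suitability map
#'
#' Annotates every ocean grid cell with the month's climatology, applies the
#' training scaling, and predicts the probability of presence with random
#' effects excluded (population-level prediction). `month = "overall"` returns
#' the mean of the 12 monthly maps.
#'
#' @param model a `hab_model`.
#' @param fields an `env_fields` (baseline or projected).
#' @param scaling scaling record from table construction.
#' @param month integer 1-12 or "overall".
#' @param region scaling-record region key.
#' @param label period label stored on the map (e.g. "baseline",
#'   "ssp585_2086-2095").
#' @return object of class `suitability_map` with a `[lon, lat]` matrix of
#'   probabilities in [0, 1], NA on land.
#' @export
predict_map <- function(model, fields, scaling, month = "overall",
                        region = "all", label = "baseline") {
  if (identical(month, "overall")) {
    monthly <- lapply(1:12, function(m)
      predict_map(model, fields, scaling, m, region, label)$values)
    vals <- Reduce(`+`, monthly) / 12
    return(structure(list(grid = fields$grid, values = vals,
                          month = "overall", label = label),
                     class = "suitability_map"))
  }
  grid <- fields$grid
  ocean <- which(!fields$land)
  nlon <- length(grid$lon)
  ci <- (ocean - 1L) %% nlon + 1L
  cj <- (ocean - 1L) %/% nlon + 1L
  nd <- data.frame(month = rep(month, length(ocean)))
  for (cv in model$hyp$covariates) {
    raw <- if (cv %in% names(fields$static)) fields$static[[cv]][ocean]
           else fields$vars[[cv]][cbind(ci, cj, month)]
    if (is.null(scaling[[region]][[cv]]))
      stop("covariate absent from scaling record: ", cv)
    nd[[cv]] <- apply_scaling(raw, scaling, region, cv)
  }
  nd$animal_id <- factor(model$id_levels[1], levels = model$id_levels)
  nd$sex <- factor(model$sex_levels[1], levels = model$sex_levels)
  nd$size_class <- factor(model$size_levels[1], levels = model$size_levels)
  re_terms <- sprintf("s(%s)", model$hyp$random_effects)
  ok <- stats::complete.cases(nd)
  pr <- rep(NA_real_, length(ocean))
  pr[ok] <- as.numeric(stats::predict(model$fit, nd[ok, , drop = FALSE],
                                      type = "response", exclude = re_terms,
                                      newdata.guaranteed = TRUE,
                                      discrete = FALSE))
  vals <- matrix(NA_real_, nlon, length(grid$lat))
  vals[ocean] <- pr
  structure(list(grid = grid, values = vals, month = month, label = label),
            class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("<suitability_map> %s (month %s): %d ocean cells, range [%.3f, %.3f]\n",
              x$label, as.character(x$month), sum(!is.na(x$values)),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Favourability transform
#'
#' Removes the dataset prevalence from predicted probabilities:
#' `F = (P/(1-P)) / (n1/n0 + P/(1-P))`. F = 0.5 where P equals the training
#' prevalence; F equals P when prevalence is 0.5. Limits P = 0 -> F = 0 and
#' P = 1 -> F = 1.
#'
#' @param map a `suitability_map` (or bare numeric vector/matrix of P).
#' @param prevalence training prevalence n1 / (n1 + n0), in (0, 1).
#' @return object of the same shape with favourability values.
#' @export
favourability <- function(map, prevalence) {
  stopifnot(prevalence > 0, prevalence < 1)
  tr <- function(P) {
    odds_data <- prevalence / (1 - prevalence)
    f <- ifelse(P >= 1, 1, ifelse(P <= 0, 0,
                                  (P / (1 - P)) / (odds_data + P / (1 - P))))
    f
  }
  if (inherits(map, "suitability_map")) {
    map$values <- tr(map$values)
    map$label <- paste0(map$label, "_favourability")
    map
  } else tr(map)
}

# rank-based AUC (Mann-Whitney)
auc_rank <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# threshold metrics at a given cutoff
threshold_metrics <- function(labels, scores, threshold) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  acc <- (tp + tn) / length(labels)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / length(labels)^2
  kappa <- (acc - pe) / (1 - pe)
  c(sensitivity = sens, specificity = spec, tss = sens + spec - 1,
    accuracy = acc, precision = prec, kappa = kappa)
}

# cutoff maximizing TSS over the observed score values
max_tss_threshold <- function(labels, scores) {
  cand <- sort(unique(scores))
  if (length(cand) > 512)
    cand <- stats::quantile(scores, seq(0, 1, length.out = 512), names = FALSE)
  ord <- order(scores)
  s <- scores[ord]; y <- labels[ord]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  cum1 <- cumsum(y == 1); cum0 <- cumsum(y == 0)
  tss_at <- function(th) {
    k <- findInterval(th, s, left.open = TRUE)   # scores < th
    sens <- (n1 - if (k > 0) cum1[k] else 0) / n1
    spec <- (if (k > 0) cum0[k] else 0) / n0
    sens + spec - 1
  }
  tss <- vapply(cand, tss_at, 0)
  cand[which.max(tss)]
}

#' Cross-validated model evaluation
#'
#' Stratified, seeded ten-fold cross-validation: the model is refitted on each
#' training split and held-out rows are scored; pooled out-of-fold predictions
#' give AUC (rank statistic), plus sensitivity, specificity, TSS, Cohen's
#' kappa, accuracy and precision at the max-TSS threshold.
#'
#' @param table PBTable.
#' @param hyp a `hypothesis_spec`.
#' @param k_folds folds (default 10).
#' @param seed fold-assignment seed.
#' @param gamma smoothness-penalty inflation passed to the fits.
#' @return list: `metrics` (named vector), `threshold`, `predictions`
#'   (out-of-fold scores aligned with `table` rows).
#' @export
evaluate_cv <- function(table, hyp, k_folds = 10, seed = 1L, gamma = 1.4) {
  stopifnot(nrow(table) >= k_folds * 10)
  assign_folds <- function(s) {
    set.seed(substream_seed(s, "cvfolds"))
    f <- integer(nrow(table))
    for (lab in c(0L, 1L)) {
      ix <- which(table$label == lab)
      f[ix] <- sample(rep_len(seq_len(k_folds), length(ix)))
    }
    f
  }
  folds <- assign_folds(seed)
  for (retry in 1:5) {
    one_class <- any(vapply(seq_len(k_folds), function(k)
      length(unique(table$label[folds == k])) < 2, TRUE))
    if (!one_class) break
    warning("fold with a single class; refolding with a new seed")
    folds <- assign_folds(seed + retry)
  }
  scores <- rep(NA_real_, nrow(table))
  for (k in seq_len(k_folds)) {
    tr <- table[folds != k, , drop = FALSE]
    te <- table[folds == k, , drop = FALSE]
    m <- fit_hab_model(tr, hyp, gamma = gamma,
                       min_presences = min(50, sum(tr$label == 1)))
    te_f <- prep_model_frame(te)
    # unseen animals are scored at the population level
    te_f$animal_id <- factor(m$id_levels[1], levels = m$id_levels)
    scores[folds == k] <- as.numeric(
      stats::predict(m$fit, te_f, type = "response",
                     exclude = sprintf("s(%s)", hyp$random_effects),
                     newdata.guaranteed = TRUE, discrete = FALSE))
  }
  th <- max_tss_threshold(table$label, scores)
  mets <- threshold_metrics(table$label, scores, th)
  mets["auc"] <- auc_rank(table$label, scores)
  list(metrics = mets, threshold = th, predictions = scores)
}

#' Continuous Boyce index
#'
#' Moving-window predicted-to-expected ratio: for each of `n_windows` windows
#' of width `window_width` times the suitability range, P = fraction of
#' evaluation presences whose suitability falls in the window and E = fraction
#' of map ocean cells in the window; the index is the Spearman correlation of
#' P/E against the window midpoint. Windows with E = 0 are skipped.
#'
#' @param map a `suitability_map` (or numeric vector of cell suitabilities).
#' @param eval_suit suitability values at evaluation presence points (>= 30).
#' @param n_windows number of windows (default 101).
#' @param window_width window width as a fraction of the suitability range
#'   (default 0.1).
#' @return Boyce index in [-1, 1].
#' @export
boyce_index <- function(map, eval_suit, n_windows = 101, window_width = 0.1) {
  cells <- if (inherits(map, "suitability_map")) as.vector(map$values) else map
  cells <- cells[!is.na(cells)]
  eval_suit <- eval_suit[!is.na(eval_suit)]
  stopifnot(length(eval_suit) >= 30)
  rng <- range(cells)
  w <- window_width * diff(rng)
  mids <- seq(rng[1] + w / 2, rng[2] - w / 2, length.out = n_windows)
  pe <- vapply(mids, function(m) {
    lo <- m - w / 2; hi <- m + w / 2
    E <- mean(cells >= lo & cells <= hi)
    if (E == 0) return(NA_real_)
    P <- mean(eval_suit >= lo & eval_suit <= hi)
    P / E
  }, 0)
  ok <- !is.na(pe)
  if (sum(ok) < 3) stop("fewer than 3 non-empty suitability windows")
  stats::cor(mids[ok], pe[ok], method = "spearman")
}
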