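test_that("collinearity screen drops one of each correlated pair", {
  set.seed(20)
  n <- 300
  a <- rnorm(n)
  tab <- data.frame(a = a, b = a + rnorm(n, 0, 0.1), c = rnorm(n),
                    d = rnorm(n))
  kept <- screen_collinearity(tab, c("a", "b", "c", "d"))
  expect_equal(sum(c("a", "b") %in% kept), 1)   # exactly one of the pair
  expect_true(all(c("c", "d") %in% kept))
  # duplicated covariate: one copy removed
  tab$a2 <- tab$a
  kept2 <- screen_collinearity(tab, c("a", "a2", "c"))
  expect_equal(sum(c("a", "a2") %in% kept2), 1)
  # independent covariates: all retained
  expect_setequal(screen_collinearity(tab, c("c", "d")), c("c", "d"))
})

test_that("Akaike weights match the closed form and its invariances", {
  fake <- function(name, aic) list(hyp = list(name = name), aic = aic,
                                   n_rows = 100)
  w <- compare_waic(list(fake("m1", 100), fake("m2", 102)))
  expect_equal(unname(w), c(exp(0), exp(-1)) / (exp(0) + exp(-1)),
               tolerance = 1e-12)
  expect_equal(unname(round(w, 4)), c(0.7311, 0.2689))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # equal AICs -> equal weights
  we <- compare_waic(list(fake("a", 50), fake("b", 50), fake("c", 50)))
  expect_equal(unname(we), rep(1 / 3, 3))
  # invariant to adding a constant to all AICs
  w2 <- compare_waic(list(fake("m1", 100 + 37), fake("m2", 102 + 37)))
  expect_equal(w, w2)
  # differing row counts rejected
  bad <- list(fake("m1", 1), list(hyp = list(name = "x"), aic = 2,
                                  n_rows = 99))
  expect_error(compare_waic(bad), "different numbers of rows")
})

test_that("favourability has the textbook closed forms and is monotone", {
  # P equal to the prevalence maps to 0.5
  for (p in c(0.09, 0.3, 0.5)) {
    expect_equal(favourability(p, prevalence = p), 0.5, tolerance = 1e-12)
  }
  # prevalence 0.5 is the identity
  P <- seq(0.01, 0.99, by = 0.01)
  expect_equal(favourability(P, 0.5), P, tolerance = 1e-12)
  # limits
  expect_equal(favourability(c(0, 1), 0.2), c(0, 1))
  # monotone increasing in P at fixed prevalence
  f <- favourability(P, 0.09)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("threshold metrics and AUC match hand-computed values", {
  tm <- pelagicshift:::threshold_metrics
  # sens 0.8, spec 0.7 -> TSS 0.5
  labels <- c(rep(1, 10), rep(0, 10))
  scores <- c(rep(0.9, 8), rep(0.1, 2), rep(0.1, 7), rep(0.9, 3))
  m <- tm(labels, scores, 0.5)
  expect_equal(unname(m["sensitivity"]), 0.8)
  expect_equal(unname(m["specificity"]), 0.7)
  expect_equal(unname(m["tss"]), 0.5)
  # perfect separation
  sep <- tm(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1), 0.5)
  expect_equal(unname(sep[c("sensitivity", "specificity", "tss", "kappa")]),
               c(1, 1, 1, 1))
  expect_equal(pelagicshift:::auc_rank(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  # shuffled labels give chance-level AUC (n = 2000)
  set.seed(30)
  lab <- rbinom(2000, 1, 0.3)
  expect_equal(pelagicshift:::auc_rank(lab, runif(2000)), 0.5,
               tolerance = 0.05)
})

test_that("fitted habitat models recover structure and reject noise", {
  w <- tiny_world()
  m <- w$model
  expect_s3_class(m, "hab_model")
  expect_true(is.finite(m$aic))
  expect_gt(m$prevalence, 0); expect_lt(m$prevalence, 1)

  # cyclic month smooth is continuous across the year boundary: the smooth
  # takes equal values at the two ends of its period (knots at 0.5 and 12.5)
  nd <- m$fit$model[c(1, 1), ]
  nd$month <- c(0.5, 12.5)
  tm <- predict(m$fit, nd, type = "terms")[, "s(month)"]
  expect_lt(abs(tm[1] - tm[2]), 1e-6)

  # SST partial response peaks near the programmed 27 C optimum
  pr <- partial_response(m, "sst", w$pb$scaling)
  peak <- pr$x[which.max(pr$effect)]
  expect_lt(abs(peak - w$truth$sst_optimum), 3)

  # shuffled labels: almost no deviance explained (null simulation)
  tab0 <- w$pb$table
  set.seed(41)
  tab0$label <- sample(tab0$label)
  m0 <- fit_hab_model(tab0, hypothesis_spec("null", m$hyp$covariates))
  expect_lt(m0$dev_expl, 5)
})

test_that("pruning removes pure-noise covariates and keeps significant ones", {
  w <- tiny_world()
  tab <- w$pb$table
  set.seed(50)
  tab$noise <- rnorm(nrow(tab))
  hyp <- hypothesis_spec("with_noise", c(w$model$hyp$covariates, "noise"))
  m <- fit_hab_model(tab, hyp)
  pruned <- prune_nonsignificant(m, tab)
  expect_false("noise" %in% pruned$hyp$covariates)
  expect_true("sst" %in% pruned$hyp$covariates)
  # alpha = 1 keeps everything
  expect_identical(prune_nonsignificant(m, tab, alpha = 1)$hyp$covariates,
                   m$hyp$covariates)
})

test_that("prediction maps are probabilities with the stated structure", {
  w <- tiny_world()
  monthly <- lapply(1:12, function(mo)
    predict_map(w$model, w$fields, w$pb$scaling, month = mo))
  overall <- predict_map(w$model, w$fields, w$pb$scaling, month = "overall")
  vals <- overall$values[!is.na(overall$values)]
  expect_true(all(vals >= 0 & vals <= 1))
  # land stays masked
  expect_true(all(is.na(overall$values[w$fields$land])))
  # overall is the mean of the 12 monthly maps
  mean_map <- Reduce(`+`, lapply(monthly, function(x) x$values)) / 12
  expect_equal(overall$values, mean_map, tolerance = 1e-9)
  # top-decile cells sit in better-than-average truth habitat
  tru <- truth_value(w$truth, w$fields$vars$sst[, , 6], w$fields$vars$chl[, , 6])
  top <- overall$values >= quantile(vals, 0.9)
  expect_gt(mean(tru[top], na.rm = TRUE), mean(tru, na.rm = TRUE))
  # a missing covariate in the scaling record is reported by name
  expect_error(predict_map(w$model, w$fields, list(all = list()), month = 1),
               w$model$hyp$covariates[1])
})

test_that("cross-validation separates signal from no-signal data", {
  w <- tiny_world()
  ev <- evaluate_cv(w$pb$table, w$model$hyp, seed = 4)
  expect_gt(ev$metrics["auc"], 0.8)
  expect_equal(unname(ev$metrics["tss"]),
               unname(ev$metrics["sensitivity"] + ev$metrics["specificity"] - 1),
               tolerance = 1e-12)
  expect_true(all(ev$predictions >= 0 & ev$predictions <= 1))
})

test_that("the Boyce index ranks proportional, uniform and inverted samples", {
  set.seed(60)
  cells <- runif(20000)
  prop <- sample(cells, 500, replace = TRUE, prob = cells)
  expect_gte(boyce_index(cells, prop), 0.9)
  inv <- sample(cells, 500, replace = TRUE, prob = 1 - cells)
  expect_lte(boyce_index(cells, inv), -0.9)
  # a single n=500 uniform draw has sd ~ 0.3; the index is centred on zero,
  # so bound the median of replicate draws
  unif <- replicate(15, boyce_index(cells, sample(cells, 500, replace = TRUE)))
  expect_lte(abs(median(unif)), 0.3)
  expect_error(boyce_index(cells, cells[1:10]), "30")
})
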