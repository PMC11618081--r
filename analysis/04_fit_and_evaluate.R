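# 04 - Fit candidate habitat hypotheses (binomial GAMs, gamma = 1.4, cyclic
# month smooth, random intercepts), compare them by Akaike weights, prune
# non-significant terms, and evaluate the winner by ten-fold cross-validation.

source("analysis/00_config.R")

tab <- read.csv(file.path(RESULTS, "pbtable.csv"))
tab$date <- as.Date(tab$date)

covs <- screen_collinearity(tab, intersect(CFG$covariates, names(tab)))
message("non-collinear covariates: ", paste(covs, collapse = ", "))

# candidate hypotheses: thermal-only, productivity-only, full suite
hyps <- list(
  hypothesis_spec("thermal", intersect(c("sst"), covs)),
  hypothesis_spec("productivity", intersect(c("chl", "sal"), covs)),
  hypothesis_spec("full", covs))
models <- lapply(hyps, function(h) fit_hab_model(tab, h))
w <- compare_waic(models)
message("Akaike weights: ",
        paste(sprintf("%s %.3f", names(w), w), collapse = ", "))

best <- models[[which.max(w)]]
best <- prune_nonsignificant(best, tab)
message(sprintf("selected '%s': %.1f%% deviance explained, prevalence %.3f",
                best$hyp$name, best$dev_expl, best$prevalence))

ev <- evaluate_cv(tab, best$hyp, seed = CFG$seed)
message("tenfold CV: ",
        paste(sprintf("%s %.3f", names(ev$metrics), ev$metrics),
              collapse = ", "))

pr <- do.call(rbind, lapply(best$hyp$covariates, function(cv) {
  p <- partial_response(best, cv, jsonlite::read_json(
    file.path(RESULTS, "scaling.json"), simplifyVector = TRUE))
  cbind(covariate = cv, p)
}))
sst_peak <- pr$x[pr$covariate == "sst"][which.max(pr$effect[pr$covariate == "sst"])]
message(sprintf("SST partial-response peak: %.2f C (truth optimum 27 C)",
                sst_peak))

write.csv(data.frame(hypothesis = names(w), waic = as.numeric(w)),
          file.path(RESULTS, "hypothesis_weights.csv"), row.names = FALSE)
write.csv(data.frame(metric = names(ev$metrics),
                     value = as.numeric(ev$metrics)),
          file.path(RESULTS, "cv_metrics.csv"), row.names = FALSE)
write.csv(pr, file.path(RESULTS, "partial_responses.csv"), row.names = FALSE)
message("wrote hypothesis_weights.csv, cv_metrics.csv, partial_responses.csv")
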