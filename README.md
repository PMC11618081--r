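# pelagicshift

Where will satellite-tracked marine megafauna find suitable habitat as the
ocean warms — and how much more will that habitat overlap with shipping?
`pelagicshift` is an R package plus a numbered analysis workflow that answers
those questions end to end for presence-only telemetry data:

1. **Track processing** — raw Argos/PSAT fixes are screened for
   floating-device tails (≥ 14 stationary days under 5 km/day), averaged to
   one position per UTC day, gap-interpolated up to 3 days, and thinned to
   ≥ 2-day separation.
2. **Presence–background tables** — background points are sampled over the
   basin (100 per presence day, cropped to ±40°, never inside the minimum
   convex polygon of presences), subsampled to a 1:10 presence:background
   ratio, and annotated with environmental covariates through each tag's
   positional-error model (100 error-randomized draws per presence), then
   winsorized, centred and scaled.
3. **Habitat models** — binomial GAMs (mgcv) with low-k smooths, smoothness
   penalty inflated by γ = 1.4, a cyclic cubic spline of month and random
   intercepts for animal/sex/size; collinearity screening (|r| ≥ 0.7),
   Akaike-weight hypothesis comparison, pruning of non-significant terms,
   ten-fold cross-validation (AUC, TSS, kappa) and the continuous Boyce
   index. Predicted probability of presence, on the logit scale

   `logit P = β₀ + Σ f(xₖ) + f_cc(month) + b_animal + b_sex + b_size`,

   is mapped at 0.25°; the favourability transform
   `F = (P/(1−P)) / (n₁/n₀ + P/(1−P))` removes prevalence where maps must be
   compared.
4. **Climate projection** — a delta-change framework over a multi-model
   ensemble (additive deltas for temperature/salinity, multiplicative for
   chlorophyll; member bias cancels) projects the baseline climatology to
   three SSPs × two decades (2046–2055, 2086–2095).
5. **Habitat change** — core habitat (≥ 90th-percentile suitability;
   50/75/95 sensitivity), spherical-area change on the 0.25° grid,
   latitudinal limit shifts in km (111.32 km/°) and km yr⁻¹, ±0.5 change
   classification, and per-region (EEZ/LME stand-in) summaries.
6. **Ship co-occurrence** — vessel counts (0.2°, fixed to the 2019 baseline)
   regridded conservatively, normalized, and multiplied by suitability
   (SCI); per-region percent change from baseline with the <0.1-in-both
   exclusion rule.

Because the real inputs (telemetry archives, ocean reanalyses, CMIP6,
vessel-traffic grids) are large and partly proprietary, the package includes
a seeded **synthetic-world generator** (`gen_env_fields`, `gen_tracks`,
`gen_climate_ensemble`, `gen_shipping`, `gen_regions`) with a known
ground-truth niche (SST optimum 27 °C, tolerance 3 °C, coastal-productivity
preference), so the whole pipeline is testable and reproducible from one
seed. See `vignettes/pelagicshift-methods.Rmd` for the model, the
assumptions, and every numerical choice.

## Worked example

The analysis drivers under `analysis/` run the full study on the synthetic
world (30 animals × ~120 days, 0.25° grid, 8-member ensemble), each script
printing what it found and writing tables under `results/`:

```sh
Rscript analysis/01_simulate_world.R      # tracks, shipping, regions
Rscript analysis/02_process_tracks.R      # daily regularized positions
Rscript analysis/03_build_model_table.R   # presence-background table
Rscript analysis/04_fit_and_evaluate.R    # GAMs, wAIC, CV skill
Rscript analysis/05_project_and_change.R  # projections, core-habitat change
Rscript analysis/06_shipping_cooccurrence.R
```

Output of a complete run (seed 1):

```
world: 200 x 360 cells, SST 11.1-30.3 C
tracks: 4754 fixes from 30 animals (20% PSAT)
4754 fixes -> 3321 regularized daily positions -> 1515 model days
model table: 1515 presences, 15150 backgrounds (0 dropped at annotation)
non-collinear covariates: sst, chl, sal
Akaike weights: thermal 0.000, productivity 0.000, full 1.000
selected 'full': 70.2% deviance explained, prevalence 0.091
tenfold CV: sensitivity 0.922, specificity 0.926, tss 0.849, accuracy 0.926,
            precision 0.556, kappa 0.655, auc 0.965
SST partial-response peak: 27.24 C (truth optimum 27 C)
baseline core habitat (q=90): 4.91 million km2 at threshold 0.337
ssp126 2046-2055: area change -0.01 Mkm2, north edge +139 km (3.61 km/yr)
ssp585 2046-2055: area change -0.03 Mkm2, north edge +473 km (12.29 km/yr)
ssp585 2086-2095: area change -0.09 Mkm2, north edge +1392 km (17.73 km/yr)
ssp126 2086-2095: mean fold change 1.01x over 2 regions; change of mean SCI +1.0%
ssp585 2086-2095: mean fold change 0.98x over 2 regions; change of mean SCI -2.7%
```

Read: the fitted model recovers the programmed 27 °C thermal optimum
(peak 27.24 °C), discriminates presences from backgrounds out of sample
(CV AUC 0.965, TSS 0.849), and under warming the core habitat's northern
(cold) edge shifts poleward at rates that grow with scenario severity —
3.6 km yr⁻¹ under sustainable development, 12–18 km yr⁻¹ under high
emissions — while co-occurrence with (fixed) shipping changes only where
lanes and habitat actually meet.

The same pipeline runs from a single call:

```r
library(pelagicshift)
res <- run_pipeline(demo_config(seed = 1, out_dir = "results/demo"))
res$habitat_change     # per scenario/decade area + shift table
res$sci_change         # per region SCI percent change
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's end-to-end demo analysis from
scratch under a given seed (synthetic world → habitat model → projections →
habitat-change and ship-co-occurrence tables) and writes the machine-readable
target report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Layout

```
R/                 package code: synthworld, trackproc, bgsample, habmodel,
                   climproj, habchange, shipco, pipeline
analysis/          numbered narrative drivers (the workflow above)
tests/testthat/    unit + property tests per module, and
                   test-acceptance.R (one block per acceptance criterion)
scripts/           acceptance.R
vignettes/         methods vignette
```
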