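---
title: "From satellite tracks to projected habitat change: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From satellite tracks to projected habitat change: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pelagicshift)
```

`pelagicshift` implements a complete presence–background species-distribution
workflow for satellite-tracked marine megafauna: telemetry regularization,
buffered background sampling, penalized binomial additive habitat models,
delta-change climate projection, core-habitat redistribution metrics, and a
ship co-occurrence index. Because the real inputs of such studies (telemetry
archives, ocean reanalyses, CMIP6 ensembles, vessel-traffic grids) are large
and often proprietary, the package ships a seeded synthetic-world generator
with known ground truth, so every stage of the pipeline is testable end to
end and the whole analysis is reproducible from one seed.

## The model

The core statistical object is a presence–background (case–control)
classifier. Presences are regularized daily track positions; backgrounds
describe the environment available to the animals. The model is a binomial
GAM on the logit scale,

$$
\mathrm{logit}\, P(y_i = 1) = \beta_0 + \sum_k f_k(x_{ik}) +
  f_{cc}(\mathrm{month}_i) + b_{\mathrm{animal}(i)} + b_{\mathrm{sex}(i)} +
  b_{\mathrm{size}(i)},
$$

with thin-plate smooths $f_k$ of the scaled environmental covariates, a
cyclic cubic spline of month (period 12, knots at 0.5 and 12.5 so December
joins January), and random intercepts for animal identity, sex and size
class. Two guards against overfitting are part of the method, not options:
the smoothness penalty is inflated by $\gamma = 1.4$, and basis sizes are
kept low ($k \le 6$). Fitting uses `mgcv` (REML below 5000 rows, fast-ML
`bam` with discretized covariates above). Predicted $P \in [0,1]$ is read as
relative habitat suitability; it depends on the training prevalence
$n_1/(n_1+n_0)$, which the favourability transform
$F = \frac{P/(1-P)}{n_1/n_0 + P/(1-P)}$ removes when maps must be compared
across datasets.

Model selection follows the study design this package reproduces: candidate
covariate sets ("hypotheses") are compared by Akaike weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$; collinear covariates
($|r| \ge 0.7$, greedy removal of the member with the higher mean absolute
correlation) never enter one model together; smooth terms with approximate
$p > 0.05$ are pruned and the model refitted once. Predictive skill is
measured by seeded, label-stratified ten-fold cross-validation (AUC by the
rank statistic; sensitivity, specificity, TSS, Cohen's kappa at the
max-TSS threshold) and by the continuous Boyce index — the Spearman
correlation of predicted-to-expected presence ratios across 101 moving
suitability windows of width 0.1 × range, with empty windows skipped.

## Track processing

Raw fixes become model data in four steps, in this order: (1) floating-device
detection — a trailing run of ≥ 14 consecutive transmitting days whose daily
great-circle displacement stays below 5 km/day marks a detached, drifting
tag; the track is cut at the first day of that run. Both thresholds are
exposed because real detachment screening is done case by case. (2) daily
regularization — all fixes within a UTC calendar date are averaged
(arithmetic mean latitude, circular mean longitude, so the antimeridian is
handled). (3) gap interpolation — runs of 1–3 missing days are filled by
linear interpolation in lon/lat and flagged; longer gaps stay open. Linear
(not great-circle) interpolation is a documented simplification, adequate
for ≤ 3-day gaps. (4) thinning — a greedy forward pass keeps days ≥ 2 days
apart to blunt serial autocorrelation. Thinning considers observed positions
only: interpolated positions are invented data and should not become model
presences. This choice also makes the processing pipeline idempotent — run
on its own output it changes nothing — which would be false if interpolated
rows could be kept, since re-interpolation would refill the 2–3-day gaps
thinning creates.

## Background sampling and annotation

The minimum convex polygon (MCP) of all daily presence positions is a
no-sampling buffer: for each presence day, 100 candidate backgrounds are
drawn over the ocean cells of the basin (cells sampled proportional to
spherical area, position uniform within the cell), rejecting points inside
the MCP or poleward of 40°, then subsampled to exactly 10 per presence
(the 1:10 presence:background ratio). Keeping whole presence-day groups when
annotation drops rows preserves that ratio exactly.

Environmental annotation is error-aware on the presence side: each presence
is replaced by 100 random locations with per-axis normal offsets of sd
1.5 × the tag's printed error radius (ARGOS 0.12°/0.12°, PSAT 1.08° lat /
0.53° lon), truncated at 3 sd — our reading of an ambiguous published rule
("the normal distribution plus half the standard deviation of the error
radius"); both the inflation and the truncation are configurable. Each
draw takes the mean of native-grid cells inside the 0.25° analysis window
(missing cells skipped; the outward-spiral enumeration of that window is
retained only for early exit on missing data — the mean itself is
order-independent, which a test asserts), and the draws are averaged.
Background points are annotated at their exact locations and share their
presence day's date for temporal interpolation, which is linear between the
two nearest mid-month climatology stamps. Covariates are then winsorized at
the 1st/99th percentiles (unstated upstream; configurable), centred and
scaled per region, and the scaling record is stored so prediction grids are
transformed identically.

## Climate projection

Future fields come from a delta-change framework: per ensemble member,
delta = future − historical (additive: temperature, salinity) or
future / historical (multiplicative: chlorophyll and other strictly positive
concentration-like variables; near-zero historical cells masked); members
are combined by arithmetic (additive) or geometric (multiplicative) mean and
the result applied to the observed baseline climatology, clamping to
physical ranges. Constant member biases cancel in the additive delta by
construction — exactly in real arithmetic, and to within 1 ulp in floating
point (bit-for-bit when all intermediate sums are representable, which the
tests verify on dyadic lattices). A single-member "ensemble" passes its
delta through unchanged, keeping the zero-noise case bit-exact. Coarse
member grids are regridded to the analysis grid by bilinear interpolation
before the delta is applied. The six projection targets are the three SSPs
(ssp126, ssp370, ssp585) × two decades (2046–2055, 2086–2095).

## Change metrics

Core habitat is the set of ocean cells at or above the 90th percentile of
suitability (sensitivity set 50/75/95), with the percentile taken either
within each projected map (where have the most important areas moved) or
from the baseline map (how much current-quality habitat remains) — the two
variants answer different questions and can disagree in sign. Percentiles
use linear interpolation between order statistics (R type 7) and ties
resolve by the ≥ rule. Areas are spherical cell areas
$R^2\,\Delta\lambda\,(\sin\varphi_t - \sin\varphi_b)$ with $R = 6371$ km on
the uniform 0.25° grid. Latitudinal limits are extreme core cell-centre
latitudes; edge shifts convert degrees to km at 111.32 km/°, signed positive
toward the nearer pole, and rates divide by midpoint-to-midpoint elapsed
years (baseline mid-year 2012.0; decade midpoints 2050.5 and 2090.5 —
denominators are config-exposed because the upstream choice is unstated).
Cellwise change maps classify |Δ| > 0.5 strictly as increase/decrease.
Zonal summaries use cell-centre region membership and area-weighted means;
coverage is core area as a percent of region ocean area.

## Ship co-occurrence

Vessel counts (annual averages on a 0.2° grid, fixed to the 2019 baseline
for all periods) are regridded to the analysis grid by overlap-area-weighted
averaging (mass-conserving where the grids tile), normalized by the global
ocean maximum of the baseline grid — computed once and reused across
periods, so the normalization cancels in the percent change of across-region
mean SCI — and multiplied by suitability: `SCI = P × ship / max(ship)`.
Regional means are unweighted cell means; percent change is reported per
region, and regions with mean SCI < 0.1 in both periods are excluded from
aggregates. Two aggregate framings are reported because both appear in
practice: the mean of per-region fold changes, and the percent change of the
across-region mean. A `log1p` count transform is available (and used in the
shipped analysis scripts) because with raw max-normalization the synthetic
world's ~1:200 background:lane contrast leaves every regional mean under the
0.1 floor; real vessel-density grids are similarly heavy-tailed.

## The synthetic world

The generator states one fixed world per seed; its defaults are the
conditions the tests assume, chosen once:

- **Grid** 0.25°, default domain 50° × 90° with the western 10% of
  longitudes as land, baseline 2005–2019, 12-month climatology.
- **Fields**: SST = meridional gradient (29 °C at the equator, −14 °C
  toward 45°, power 1.5) + seasonal sinusoid (amplitude up to 3 °C, phase
  opposite between hemispheres) + N(0, 0.3) noise; chlorophyll = coastal
  exponential decay (e-folding 4°) with mild seasonality and lognormal
  noise, strictly positive; salinity with subtropical maxima; static
  bathymetry deepening offshore.
- **Truth niche**: logit suitability = 0.5 + 0.5·log(chl) −
  ((SST − 27)/3)², i.e. a 27 °C thermal optimum with 3 °C tolerance and a
  coastal-productivity preference.
- **Tracks**: daily biased random walk; candidate steps (uniform heading,
  half-normal length, scale 0.7°) are accepted with probability
  `plogis(4 × truth logit)` — bias strength 4 gives strong but not
  deterministic habitat preference; 0 gives unbiased movement (a test
  checks occupied SST is then indistinguishable from availability).
  Transmission gaps are geometric (~20% of days missing, mean length 2,
  exercising both sides of the 3-day interpolation rule). Floating tails,
  when injected, carry surface-quality fixes (0.01°, 4–8 fixes/day):
  a detached tag floats and transmits continuously, and without that the
  5 km/day detector could never see a tail under 0.12–1.08° at-depth
  observation error.
- **Ensemble**: 8 members with constant biases spread over ±1 °C;
  end-of-century deltas ssp126 +0.8 °C / chl ×0.95, ssp370 +2.0 °C / ×0.85,
  ssp585 +3.2 °C / ×0.75 (CMIP6-like magnitudes), mid-century at half the
  end-of-century change; members generated on the analysis grid so
  zero-noise identities are exact.
- **Shipping**: 0.2° grid, background 2 vessels/cell, 3 Gaussian lanes
  (peak 400, sd 1°). **Regions**: disjoint rectangles tiling the ocean.

What the generator does *not* emulate: ocean dynamics (no currents, eddies
or fronts), realistic bathymetry, behavioural state switching, Argos
quality classes (inputs are taken as pre-filtered), and the full 28-variable
covariate suite of the real analysis — a green test therefore establishes
that the pipeline recovers a known niche and propagates change correctly,
not that any particular real-world covariate set would be selected.

## Numerical choices and edge cases

- Percentile thresholds: type-7 linear interpolation; uniform maps make
  every cell core under the ≥ rule.
- Favourability limits: P = 0 maps to 0, P = 1 to 1.
- Boyce windows with zero expected mass are skipped; fewer than 3 non-empty
  windows is an error. Under uniform evaluation sampling a single n = 500
  draw of the index has sd ≈ 0.3 (the 101 windows overlap ~10-fold), so
  null-centredness is asserted on replicate means, not single draws.
- Cross-validation folds are label-stratified and seeded; a single-class
  fold triggers a warned refold.
- Random effects are excluded (set to their population level) at
  prediction, so maps are population-level; unseen animals in CV test folds
  are scored the same way.
- Zero-variance covariates abort scaling with the covariate named;
  annotation drops whole presence-day groups so the 1:10 ratio survives.
- All stage substreams derive from one master seed (`substream_seed`), so
  identical configurations reproduce identical outputs bit for bit while
  stages stay independent.

## Limitations

Rectangular regions and a meridian coast are deliberate simplifications;
region polygons are only stand-ins for EEZ/LME geometry. Gap interpolation
is planar. The SCI is a static co-occurrence screen, not a collision-risk
model: it ignores vessel and shark movement dynamics and the vertical
dimension. Latitudinal limits use cell centres; with 0.25° cells the
difference from edges is below the metric's meaningful resolution.
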