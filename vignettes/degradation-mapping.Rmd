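---
title: "Mapping cropland degradation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cropland degradation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`degrisk` detects negative vegetation trends in irrigated cropland from
16-day vegetation-index composites and models the spatial pattern of the
detected degradation with a logistic regression on environmental and
management factor grids. This vignette records the models, their
assumptions, the parameters that matter, and the design decisions taken
where several defensible choices existed.

## Stage 1: the trend model

The quantity analysed per pixel is the growing-season sum of the
smoothed vegetation index, ΣNDVI, one value per year. In arid
irrigated systems ΣNDVI is a serviceable proxy for annual vegetation
production, so a sustained decline is read as land degradation. The
model is ordinary least squares on the year index $t = 0, \dots, k-1$:

$$\Sigma\mathrm{NDVI}_t = \beta_0 + b\,t + \varepsilon_t,$$

so $\beta_0$ is the fitted vegetation level at the first year of the
series. The slope's $t$ statistic uses $k-2$ degrees of freedom and a
two-sided $p$ value. Assumptions worth stating: the trend is linear in
time, errors are independent between years (16-day autocorrelation is
largely integrated away by the seasonal sum), and the management regime
is stable enough that a decline is not a rotation artefact — summing
over the whole season, across crop peaks, is what buys that robustness.

**Classification.** Negative slopes are cut at two-sided $p \le 0.05$
(high severity, 95 % confidence), $p \le 0.10$ (medium, 90 %), else low;
non-negative slopes are "other" and deliberately outside scope. High and
medium merge into the binary degraded map that stage 2 explains. A
slope of exactly zero is "other": the severity classes are defined on
the *negative* slope only. Under a pure-noise cube these cuts put 2.5 %
of pixels in the high class and 5 % in high+medium (the negative tail
halves the two-sided rates); the test suite verifies both.

**Pre-processing.** Quality flags map to fit weights (default
pixel-reliability style: 0 → 1.0, 1 → 0.5, 2 and 3 → 0, i.e. missing).
Gaps are filled by linear interpolation in time; leading/trailing gaps
hold the nearest valid value rather than extrapolate, precisely because
series endpoints have the greatest leverage on a trend. Filled points
enter the smoother at the smallest positive weight present in the
cube's weighting scheme, so they anchor continuity without steering the
fit. Pixels with fewer than two valid observations are masked
throughout.

**Smoothing.** The weighted Savitzky–Golay filter replaces each point
by the value of a degree-2 weighted least-squares polynomial over a
window of `2*half_window + 1 = 9` composites, truncated at the series
ends. With `envelope_iters > 0`, points below the current fit have
their weights multiplied by `weight_decay` (default 0.5) and the fit is
repeated — the upper-envelope adaptation appropriate when artefacts
(cloud, snow) only depress the index. Defaults (`half_window = 4`,
`poly_order = 2`, `envelope_iters = 2`) follow common practice for
16-day composites; none is prescribed by theory and all are exposed in
the configuration. With `envelope_iters = 0` and uniform weights the
filter is linear and reproduces polynomials up to the fitted degree
exactly; both properties are tested and the second is what makes the
zero-noise closed-loop check exact.

**Season membership** is decided by the composite *start date*
(April 1 – October 31 inclusive): 16-day composites straddle month
boundaries, and a single unambiguous rule beats any proration. With 23
composites per year this yields 13 in-season composites.

**Endpoint sensitivity.** Because first/last years dominate a linear
trend, the class map is recomputed dropping the first and, separately,
the last year; agreement is the plain percentage of identically
classified cells. No further weighting is applied — overall accuracy is
the simplest statistic that answers "would the map change?".

**Areal statistics** convert cell counts to hectares
(`cell_size²/10⁴`; 6.25 ha at 250 m) per district zone, with percent of
the zone's unmasked cells, a combined medium+high column, and a TOTAL
row. District zones are rasterized by the cell-center rule (a cell
belongs to the polygon containing its center) — unambiguous and
area-preserving on average; the source analyses do not state their
rule, so this one is the package's own.

## Stage 2: the logistic risk model

Degradation presence $y \in \{0,1\}$ is modelled as

$$P(y=1 \mid x) = \frac{1}{1 + e^{-(\beta_0 + \sum_i \beta_i x_i)}},$$

with the x1…x18 vocabulary: land-use no-change flag, uncultivated flag,
four soil-fertility (bonitation) class dummies, canal and collector
densities (m/m²), district water-use delta (million m³), slope (%),
groundwater table (m) and salinity (g/l), and six distance layers (m).

- **Sampling.** One random unmasked cell per 3 × 3 block (750 m at
  250 m cells). Logistic ML assumes independent observations; NDVI
  trends and factor fields are spatially autocorrelated well beyond one
  cell, and block thinning is a cheap, transparent mitigation. The
  sample is split 50/50 into calibration and validation.
- **Collinearity.** Iterated VIF screen at threshold 5, each VIF being
  $1/(1-R_j^2)$ from the auxiliary regression of predictor $j$ on the
  rest; exact collinearity (e.g. the four bonitation dummies plus the
  intercept) appears as infinite VIF and is removed first, which is why
  one dummy always leaves the model.
- **Fitting.** Maximum likelihood by IRLS (relative deviance change
  < 1e-8, ≤ 100 iterations) through the standard `glm` machinery;
  standard errors from the inverse observed information. Complete
  separation surfaces as a non-convergence warning rather than an
  error, matching how practitioners triage it.
- **Stepwise variant and comparison.** Backward elimination drops the
  largest Wald $p > 0.05$ until none remains (the removal α is a
  package choice, configurable). Full and reduced models are compared
  on the validation rows with a paired z test of the correlated AUCs
  using the DeLong placement-variance estimator; when the test is
  significant the higher-AUC model wins, otherwise parsimony does. The
  quantitative rule is the package's reconstruction of the qualitative
  practice of keeping the better-discriminating model.
- **Validation.** Rank-based AUC (ties count ½), PCP at the
  conventional 0.5 probability cut, and the whole-model likelihood
  ratio against the intercept-only model with df = number of slopes.
  Hosmer–Lemeshow-style grouped tests are deliberately not implemented.
- **Odds.** Coefficients are reported as percent odds change
  100·(e^β − 1), with significance stars at p < 0.1 / 0.05 / 0.01 /
  0.001.
- **Risk map.** Model probabilities over the factor grids, ranked
  descending with ties broken by (row, column), cut into ten
  equal-count classes; class 1 is the top decile of risk. Class sizes
  stay within one cell of N/10 by construction.

## The synthetic scenario

`scenarioConfig()` fixes the study conditions: a 120 × 120 grid of
250 m cells, years 2000–2010, 23 composites per year with the
April–October season holding 13 of them, composite noise σ = 0.05
NDVI, 5 % missing and 10 % marginal-quality observations (the latter
additionally depressed by U(−0.2, 0) to emulate residual cloud),
latent factor fields as Gaussian-blurred white noise rescaled to
plausible ranges (groundwater table 0.8–2.5 m, salinity 0.5–4 g/l,
slope 0–3 %), 500 wells, ten Voronoi districts, and true logistic
coefficients set to the published headline effect sizes (β₀ = −3.55;
groundwater table 1.46, uncultivated 0.71, slope 0.25, salinity 0.23,
no-change 0.14). With those ranges the linear predictor centers near
zero, so scenario prevalence sits near 50 % — higher than a typical
real region, which is acceptable for power but worth remembering when
comparing validation metrics with published regional values.

Each cell's NDVI series is `baseline + A_t · pulse + noise`, a constant
bare-soil floor (0.12) plus a fixed mid-season pulse whose amplitude
declines linearly. Two design choices make the closed loop *exact* at
zero noise: the pulse is supported on composites 11–15 only, placed so
that every in-season smoothing window is complete and entirely
in-year, and the composite calendar is anchored to one 365-day
template so leap years do not slide a 14th composite into the season.
Under those conditions the seasonal sum of the smoothed series is an
exact linear functional of the planted amplitude, and the recovered
ΣNDVI slope equals the planted one to machine precision — the test
suite asserts 1e-6. Degraded cells draw slopes from U(−0.24, −0.08)
ΣNDVI/yr (chosen so amplitudes stay positive over 11 years and the
slope t statistic sits far outside the classification cut), stable
cells from U(0, 0.04) — a slight greening, so the stable class is not
knife-edge at zero and false positives stay well under the nominal
5 %.

What the generator does *not* emulate: sensor geometry and gridding
artefacts, crop phenology differences between fields, spatially
correlated cloud masks, label noise in the outcome (labels follow the
logistic model exactly), and any coupling between land use and the
NDVI amplitude. Passing tests therefore demonstrate correctness of the
algorithms under known structure, not skill on any particular real
region.

## Numerical choices

- **GeoTIFF I/O** is a minimal uncompressed single-band implementation
  (ModelPixelScale/ModelTiepoint geotransform, GDAL-style nodata tag,
  CRS carried as an opaque citation string compared for equality only;
  no reprojection). Continuous layers default to float64 so write/read
  round-trips are lossless; class layers use uint8/int16.
- **Geometry.** Segment-to-cell clipping is Liang–Barsky on closed
  rectangles; zone membership is even-odd ray casting at cell centers;
  distances are exact center-to-center minima.
- **Variogram fitting** is method-of-moments binning followed by
  weighted least squares with Cressie-style weights (pair count over
  squared lag), a normalized objective, and a three-point multi-start
  on the range — plain pair-count weights let the flat large-lag bins
  swamp the range information, and an unscaled objective can defeat
  L-BFGS-B's stopping rule.
- **Kriging** is ordinary (unknown mean) with a moving neighborhood of
  the 16 nearest wells; γ(0) = 0 so a zero-nugget model interpolates
  exactly; coincident wells are averaged before solving.
- **Trend edge cases.** A numerically perfect line gets p = 0 with an
  infinite-t sentinel; a constant series gets slope 0, p = 1.
- **Decile ties** are broken by (row, column) order so the map is
  deterministic.
- **Seeds.** Every stochastic operation takes an explicit seed;
  `makeScenario()` derives all internal seeds from the one
  configuration seed, and the run manifest records it.

## Problem sizes

The test suite runs the full two-stage loop on the default 120 × 120
scenario (≈ 90,000 ha; 1,600 block samples, 800 calibration rows) and
the coverage simulation at n = 4,056 with 100 replicates; unit tests
use 5–40 cell grids where exactness, not power, is the point. These
sizes keep a complete run in the low minutes on one core while leaving
the statistical checks (type-I rates, coverage, recovery within 2 SE)
properly powered.

## Known limitations

Positive/neutral trend analysis, alternative smoothers and robust trend
estimators (Theil–Sen, Mann–Kendall), spatially correlated-error
logistic models (autologistic, GEE), universal kriging and anisotropy,
reprojection/resampling, and multi-threshold PCP curves are out of
scope. The odds interpretation is per-unit-of-predictor and inherits
whatever scaling the factor layers carry; the package does not
standardize predictors.
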