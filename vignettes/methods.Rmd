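---
title: "Methods: drought indices, CASA NPP and their coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought indices, CASA NPP and their coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data tests do and do not demonstrate
about real data.

## Data model

All gridded inputs live in a `grid_cube`: a `(time, row, col)` array with an
explicit, gap-free `(year, month)` calendar, a `grid_meta` geometry (row 1
is the northernmost row; cell-centre latitude is used wherever latitude is
needed), and `NA` as the in-memory mask. Two cubes are combinable only if
their geometry matches exactly; nothing in the package resamples silently,
because silent resampling is the classic source of irreproducible raster
analyses. A nearest/bilinear `resample_field()` utility exists for explicit
pre-alignment only.

On disk, fields are ESRI ASCII grids (text, written at `%.17g`, so a round
trip is bit-identical) or two-channel 32-bit TIFFs (scaled values + validity
mask, with a JSON sidecar for geometry and scaling). The TIFF route
round-trips to about 1e-9 relative precision because the TIFF writer stores
scaled integer samples; the ASCII route is the lossless reference format.

## CASA NPP

Monthly NPP is `APAR × ε` with `APAR = 0.5 · SOL · FPAR` (half of total
solar radiation is photosynthetically active) and
`ε = T₁ · T₂ · W · ε_max(class)`.

* **FPAR** is the α-weighted mean (default α = 0.5) of two clamped
  estimates: the NDVI ramp between per-class `(NDVI_min, NDVI_max)` and the
  analogous ramp on the simple ratio `SR = (1+NDVI)/(1−NDVI)` (NDVI clamped
  to ≤ 0.99 first). Per-class NDVI bounds default to the 5th/95th
  percentiles of that class's record — robust to outliers and standard CASA
  practice — and can be fixed explicitly.
* **Optimal temperature** per pixel is the mean air temperature of the
  calendar month whose multi-year mean NDVI is maximal; ties break to the
  earliest month for determinism.
* **Temperature stress**: `T₁ = 0.8 + 0.02·Topt − 0.0005·Topt²` and
  `T₂ = 1.1814 / (1+exp(0.2(Topt−10−T))) / (1+exp(0.3(−Topt−10+T)))`,
  both clamped to ≥ 0. `T₂` can marginally exceed 1 (≤ ~1.005) in a narrow
  band just above the optimum; we do not clamp it to 1.
* **Water stress** defaults to the precipitation/PET mode, because the
  classic CASA input list contains no soil moisture:
  `W = 0.5 + 0.5·EET/PET` with the Zhou–Zhang coupling
  `EET = P·Rn·(P²+Rn²+P·Rn)/((P+Rn)(P²+Rn²))` and the net-radiation proxy
  `Rn = PET·(a + b·P/PET)`. The defaults `a = 0.4, b = 0.3` are a heuristic
  choice made once — net radiation scales with atmospheric demand and
  increases somewhat with moisture supply — and are exposed in
  `casa_params()`; they are an assumption of this package, not a published
  calibration. A `soil_moisture` mode
  (`W = 0.5 + 0.5·SM/SM_p95`) is provided for sensitivity analysis.
  Months with `PET ≤ 0` get the fully stressed floor `W = 0.5`.
* **ε_max** defaults (gC/MJ): farmland 0.542, woodland 0.692, grassland
  0.542, in the lineage of modified-CASA parameterizations for East-Asian
  vegetation; all configurable. Non-vegetated classes (water, construction,
  ice/bare) are masked, not zero-filled, so they never dilute regional
  means.

Annual NPP is the per-pixel sum of 12 monthly values; a single masked month
masks the year.

## PET and SPEI

PET uses the Thornthwaite method — temperature and latitude only — because
it is the minimal-input standard for SPEI construction. The heat index is
computed from multi-year mean monthly temperatures; months at or below 0 °C
contribute nothing and get PET = 0. The single power-law form is used for
all T > 0 (the classic high-temperature polynomial branch above 26.5 °C is
omitted; at the monthly means this package targets the difference is a few
percent in the hottest months). The day-length correction uses the
sunset-hour-angle formula at cell-centre latitude and is undefined poleward
of 66.5°, which is a hard error.

SPEI at scale k accumulates `D = P − PET` over k months (the first k−1
steps are masked), then fits, per pixel and calendar month, a
three-parameter log-logistic distribution by L-moments (unbiased
probability-weighted moments) and maps the fitted cumulative probability to
a standard normal deviate via the classical rational approximation
(c₀ = 2.515517, c₁ = 0.802853, c₂ = 0.010328, d₁ = 1.432788, d₂ = 0.189269,
d₃ = 0.001308). The fit reference period is the full record, matching
product-style SPEI datasets.

Three numeric-safety rules were needed to make small-sample (20-year)
calibration behave, and are part of the method definition here:

1. **Mirrored fallback.** The log-logistic can only represent positive
   L-skew. Long accumulations are nearly symmetric, so roughly half of all
   strata have negative sample L-skew and the direct fit is invalid; such
   strata are fitted on the negated series and the deviate's sign flipped.
2. **Support fallback.** When a fitted location parameter lies above the
   sample minimum, in-sample points below it have no fitted probability;
   they receive Gringorten plotting positions `(r − 0.44)/(n + 0.12)`.
3. **Tail shrinkage.** Within the fit reference sample, fitted tail
   probabilities are bounded by half the plotting position (both tails), so
   a 20-value stratum cannot assign quasi-impossible probabilities
   (|z| > 4) to values it actually contains; with n = 20 in-sample deviates
   are bounded near ±2.2. A running-maximum guard keeps the final
   probabilities monotone in the data, so ranks are always preserved.
   Probabilities are additionally clipped to `[1e-6, 1 − 1e-6]`.

Strata that are too short (< 8 values) or have zero variance are masked and
counted in a warning.

## SSMI, grades, DFI, aridity

SSMI is the per-stratum z-score of the k-month rolling mean of soil
moisture. The standardization stratum is ambiguous in common usage between
whole-series and calendar-month grouping; calendar-month is the default
(each month's output has mean 0, SD 1 exactly over the record, and the
seasonal cycle cannot masquerade as drought), with `stratum = "all"` as the
alternative.

Severity grades: SPEI — none (> −0.5], mild (−1, −0.5], moderate
(−1.5, −1], severe (−2, −1.5], extreme (≤ −2); SSMI differs only in the
mild/none boundary at 0. All boundaries closed on the dry side, exactly as
printed in the grade tables the scheme follows. The drought-frequency map
is `DFI = 100·m/M` with the threshold defaulting to −1 (a configurable
override to −0.5 exists because drought-area analyses often count mild
droughts too — the two conventions are surfaced, not merged). Aridity
classes are humid (< 1), semi-humid [1, 1.5), semi-arid [1.5, 4),
arid (≥ 4).

Seasons are meteorological (MAM/JJA/SON/DJF, December belonging to the
following year's winter); multi-season historical events are handled by the
event catalog instead of a season re-definition.

## Trends, correlations

Trends use Theil–Sen slopes (median of pairwise slopes) with tie-corrected,
continuity-corrected Mann–Kendall tests, applied to annual aggregates (sum
for fluxes, mean for states) so slopes carry per-annum units; the standard
mapping convention of four significance classes uses α = 0.05 by default. Pixel
trends use annual series because printed trend rates are per annum; monthly
trends are possible by passing fractional-year time coordinates.

Correlation fields are per-pixel across years: plain Pearson with
`t = r√((n−2)/(1−r²))`, and partial correlation from the inverse joint
correlation matrix with `df = n − 2 − #controls`. Constant controls are
dropped per pixel (so degenerate controls reduce to plain Pearson), and
singular matrices mask the pixel. Season-to-index alignment: a 3-month
index at a season's final month (May/Aug/Nov/Feb, February taken from the
following calendar year for winter) represents that season; a 12-month
index at December represents the year. Correlations are per-pixel over
years — the only construction consistent with mapped correlation fields.
No multiple-testing correction is applied to significant-area fractions;
they are raw p < α fractions by design.

## ΔNPP tables and skill validation

The non-drought baseline is the mean NPP per (vegetated class × calendar
month) over all pixels and years with severity "none" — pooled over space
because per-pixel baselines would be noisy on short records. ΔNPP for a
drought pixel-month is the percent departure from its class-month baseline;
tables aggregate means per (class, severity[, month]), and rows with no
contributing pixel-months are absent rather than zero. The early-season
(Mar–May) versus peak-season (Jun–Aug) comparison reports which window is
more negative per class × severity.

Event-detection skill reduces the index cube to one regional flag per month
— either mean index ≤ τ (default −0.5) or area fraction at mild-or-worse
≥ φ (default 0.3); both rules are provided because published validations
rarely state theirs — and counts month-level hits/misses/false alarms
against the catalog. Month-level counting was chosen over event-level
counting for determinism and auditability: POD, FAR and CSI then follow
their count identities exactly, and scores with zero denominators are
absent rather than zero.

## The synthetic generator

`generate_synthetic()` emulates a 2001–2020 warm-temperate semi-humid
scenario: temperature with a July-peaked seasonal cycle (mean 10.74 °C,
semi-amplitude 14 °C, trend +0.02 °C/a, white noise SD 0.8 °C);
precipitation with a summer-concentrated monthly climatology summing to
580.52 mm/a (+2.65 mm/a trend), drawn as gamma deviates (shape 2.5, so the
marginal is right-skewed as real monthly precipitation is); solar radiation
430 ± 180 MJ m⁻² month⁻¹; soil moisture from a leaky bucket
`SM_t = min(cap, (1−λ)SM_{t−1} + βP_t − γPET_t)` clipped at 0, with PET the
package's own Thornthwaite output so SSMI and SPEI are physically coupled;
and NDVI as a class-specific logistic function of the standardized 3-month
precipitation anomaly (grassland most sensitive, woodland least), clipped
to [0.01, 0.95] on vegetated classes and ≈ 0 elsewhere. Six region-wide
drought episodes (deficit fractions 0.4–0.5, including two cross-year
winter events) multiply precipitation over their spans; the truth record
and `make_event_catalog()` expose them for validation. Land cover defaults
to six equal class bands. Noise is spatially white by default with an
optional Gaussian-blur correlation length, so downstream pixel statistics
see controllable spatial independence. The bucket and climate parameters
were chosen once to keep soil moisture inside a physical 0–0.45 m³ m⁻³
range with a realistic seasonal cycle.

What the generator does *not* emulate: weather-generator autocorrelation
beyond the bucket recursion, topographic climate gradients, spatially
correlated drought onset, land-cover change, or sensor artifacts in NDVI.
Tests that pass on this synthetic ground truth therefore demonstrate
algorithmic correctness and statistical calibration — not that the default
CASA parameterization is unbiased for any particular real region.

## Problem sizes and determinism

The default pipeline scenario is a 24 × 24 grid × 240 months — small enough
for interactive runs and exhaustive testing while leaving every calendar
stratum its full 20 samples; calibration experiments use 500–2000 pixels
and 5000 Monte-Carlo replicates. All randomness flows from the single run
seed, and the pipeline manifest records an MD5 checksum per artifact;
re-running a config with the same seed must reproduce identical checksums,
which the test suite asserts.

## Known limitations

* The CASA stress parameterization (`T₁`, `T₂`, the Rn proxy, ε_max table)
  is one defensible member of a family; regional applications should treat
  `casa_params()` as a calibration surface.
* Thornthwaite PET underestimates demand in windy/arid conditions and knows
  nothing of radiation; SPEI built on it inherits that dialect.
* The log-logistic tail rules bound in-reference-sample deviates (±2.2 at
  n = 20), so "extreme" grades are rare by construction on short records.
* Mann–Kendall p-values assume serial independence; prewhitening variants
  are out of scope.
* No reprojection: inputs must share one grid before entering the package.
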