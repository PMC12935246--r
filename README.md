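# droughtnpp

Drought characteristics and their impact on vegetation net primary
productivity (NPP), as a reusable gridded pipeline in R.

The package is aimed at ecohydrologists and carbon-cycle analysts who work
with monthly raster stacks of precipitation, air temperature, solar
radiation, surface soil moisture and NDVI over a study region, and who want
to quantify (i) where and how often drought occurs, (ii) how vegetation
productivity is trending, and (iii) how strongly drought of each severity
depresses productivity in each vegetation type.

## What it computes

**CASA NPP.** Monthly NPP from the Carnegie–Ames–Stanford light-use-efficiency
model,

    NPP(x,t) = APAR(x,t) × ε(x,t),      APAR(x,t) = 0.5 · SOL(x,t) · FPAR(x,t)

with `ε = T₁ · T₂ · W · ε_max(class)`: FPAR estimated from NDVI (blend of the
NDVI ramp and simple-ratio estimates), temperature stress scalars built
around the per-pixel optimal temperature (the month of maximal multi-year
mean NDVI), and a water-stress scalar `W ∈ [0.5, 1]` from either a
precipitation/PET evapotranspiration coupling or soil moisture.

**Drought indices.** SPEI at 1/3/12-month (or any) scales — the k-month
accumulated water balance `D = P − PET` (Thornthwaite PET) fitted per pixel
and calendar month with a three-parameter log-logistic distribution by
L-moments and mapped to standard-normal deviates — and SSMI, the per-stratum
z-score `(SM − SM̄)/σ` of k-month soil moisture. Both are classified into
mild/moderate/severe/extreme grades (boundaries at −0.5/−1/−1.5/−2 for SPEI;
0/−1/−1.5/−2 for SSMI, closed on the dry side) and summarized as
drought-frequency maps `DFI = 100·m/M` and drought-area time series.

**Statistics.** Per-pixel Theil–Sen slopes with tie-corrected Mann–Kendall
significance; Pearson and partial correlation fields of annual NPP against
precipitation, temperature and radiation; seasonal SPEI-3/NPP correlation
maps; ΔNPP tables (mean percent NPP anomaly relative to the non-drought
class × calendar-month baseline, by vegetation type and severity); and
POD/FAR/CSI skill of catalog-based drought detection.

**Synthetic scenarios.** `generate_synthetic()` builds 2001–2020 monthly
cubes with seasonal cycles, prescribed trends, gamma-like precipitation,
a leaky-bucket soil moisture coupled to PET, class-specific
NDVI–precipitation coupling and embedded drought episodes — so every stage
of the chain has recoverable ground truth.

## Worked example

```r
library(droughtnpp)
cfg <- run_config(seed = 7, out_dir = "run1")   # default synthetic scenario
run_pipeline(cfg, quiet = TRUE)
summarize_run("run1")
```

```
droughtnpp run summary (seed 7)
  mean annual NPP: 376.05 gC m-2 a-1 (Sen slope +1.359 per a)
  NPP trend classes: sig_increase 4.5%, nonsig_increase 72.9%, nonsig_decrease 22.2%, sig_decrease 0.3%
  mean drought frequency (SPEI-1): 17.1%
  drought detection: POD 0.9231, FAR 0.0000, CSI 0.9231
```

Reading the output: regional mean annual NPP is ~376 gC m⁻² a⁻¹ and creeping
upward (+1.4 gC m⁻² a⁻¹, the Theil–Sen slope of the regional series), driven
by the configured warming/wetting trends; about 17% of months fall below the
SPEI-1 drought threshold (−1); and the SPEI-1 regional flag detects the six
embedded drought episodes with a 0.92 hit rate and no false alarms. All
rasters, CSV tables and a checksummed `manifest.json` land in `run1/`;
re-running with the same seed reproduces identical checksums.

The same chain runs on real data by passing `inputs =` (glob patterns for
per-month rasters plus a land-cover raster and an event-catalog CSV) instead
of `synthetic =`. Inputs must be pre-aligned on one grid: the package
refuses to resample silently.

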