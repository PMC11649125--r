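---
title: "Modelling grassland aboveground biomass: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling grassland aboveground biomass: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grassagb)
```

## The problem

Grassland aboveground biomass (AGB, g dry matter/m²) is the standard field
indicator of grassland condition, but direct measurement does not scale to
regional records spanning decades. The established remote-sensing route is a
light-use-efficiency (LUE) model of the CASA family: monthly net primary
productivity is the product of absorbed photosynthetically active radiation
and a stress-scaled efficiency,

$$\mathrm{NPP}(x,t) = \mathrm{APAR}(x,t) \times \varepsilon(x,t),$$

followed by an allocation step that converts production carbon into standing
aboveground biomass via per-type root:shoot ratios, and a set of per-pixel
statistics that characterise trends, stability and drivers. `grassagb`
implements that whole chain as a tested pipeline, together with a
synthetic-scenario generator that emulates the inputs (NDVI with gaps and
spikes, meteorology with configurable trends, two-layer soil moisture, a
grassland-type mosaic) and stores ground truth, so every stage can be
verified quantitatively without any external download.

## Model components

### NDVI preprocessing

Composite NDVI records carry dropouts and cloud/atmosphere spikes. The
cleaning chain runs per pixel, in this order: linear gap filling (interior
gaps interpolated between nearest observations; record ends take the nearest
value — extrapolating a trend beyond the record ends amplifies noise, so the
edge rule is deliberately flat), interquartile-range outlier screening with
the type-7 (linear interpolation) quantile rule and fence multiplier
`k = 1.5`, re-interpolation of removed cells, Savitzky–Golay smoothing
(window 5, degree 2 by default; both exposed), and maximum-value compositing
to monthly cadence. Outliers are screened *after* the first fill so that
spikes cannot anchor the interpolation, and the composite comes last so the
monthly product reflects cleaned data.

Two choices deserve emphasis:

* **Screening scope.** The IQR screen can be applied to a pixel's full
  record (`scope = "full"`) or within each composite period-of-year across
  years (`scope = "seasonal"`, the default). On a seasonal signal the
  full-record fence sits far above dormant-season values, so a doubled
  winter value (say 0.12 → 0.24) is arithmetically inside the fence and
  undetectable in principle; screening each calendar period against its own
  inter-annual distribution gives every cell a meaningful reference. The
  vector-level `remove_outliers_iqr()` is the plain full-record primitive.
* **Smoothing is not a projection.** Savitzky–Golay reproduces polynomials
  up to its degree but attenuates sharper curvature, so the cleaning chain
  is *not* exactly idempotent: a second pass changes the series again,
  strictly less than the first (a contraction). The tests assert exactly
  that, plus the fact that filling and screening are true no-ops on clean
  data.

Meteorological fields are averaged (temperature, humidity) or accumulated
(precipitation, radiation) to months; vapour pressure deficit uses the
Tetens saturation curve, $e_s(T) = 0.6108\,e^{17.27T/(T+237.3)}$ kPa, with
$\mathrm{VPD} = e_s(T)(1 - \mathrm{RH}/100)$ — the standard psychrometric
definition, chosen because it needs only variables the pipeline already
carries and is trivially swappable. The two ERA5-Land-style soil-moisture
layers combine with thickness weights $7/28$ and $21/28$. Station records,
if used instead of gridded inputs, are gridded by inverse-distance weighting
(power 2, eight nearest stations) — a deliberately simple, dependency-free
replacement for spline-based interpolation suites, adequate at the desk
scales this package targets.

### The productivity model

The published chain fixes only the top-level product; the internals follow
the standard CASA formulation and are all parameterised:

* **FPAR** is the linear NDVI ramp between `ndvi_min = 0.05` and
  `ndvi_max = 0.75`, mapped onto `[0.001, 0.95]` and clipped. Ramp anchors
  are per grassland type in `casa_params()`.
* **APAR** = SOL × FPAR × 0.5, the PAR fraction of shortwave radiation.
* **Temperature stress** uses the two classic factors: a fixed penalty of
  the pixel's thermal optimum $T_{opt}$,
  $0.8 + 0.02\,T_{opt} - 0.0005\,T_{opt}^2$ (floored at 0, and forced to 0
  in months at or below −10 °C), and a logistic penalty for departure from
  the optimum, $1.1814/[(1+e^{0.2(T_{opt}-10-T)})(1+e^{0.3(-T_{opt}-10+T)})]$.
  $T_{opt}$ defaults to the pixel's mean temperature in its NDVI-peak month
  (a fixed override is available).
* **Water stress** scales estimated actual over potential
  evapotranspiration into $[0.5, 1]$: $W = 0.5 + 0.5\,E/E_p$ with
  $E = \min(\mathrm{PPT}, \mathrm{PET})$ — a deliberate simplification that
  needs no soil water balance — or, alternatively, relative soil moisture
  $0.5 + 0.5\,\mathrm{SM}/\mathrm{SM}_{fc}$. PET is Hamon's
  temperature-and-day-length formula, again because it requires nothing the
  pipeline does not already have.
* **Maximum light-use efficiency** defaults to 0.542 g C/MJ for grassland.

These defaults are documented assumptions from the classic CASA grassland
lineage, not a reconstruction of any particular author configuration; every
constant is exposed through `casa_params()` and the pipeline configuration.

### Allocation, carbon and grazing intensity

The conversion from production carbon to standing biomass has an ambiguous
printed form in parts of the literature, so two readings are implemented
behind a strategy switch:

* `carbon_partition` (default): production carbon splits between layers in
  proportion to the root:shoot biomass ratio with layer-specific carbon
  fractions, giving $\mathrm{AGB} = \mathrm{NPP}/(C_a + (R/S)\,C_b)$. This
  is the only reading that closes the carbon budget exactly
  ($C_a\,\mathrm{AGB} + C_b\,(R/S)\,\mathrm{AGB} = \mathrm{NPP}$, asserted
  per pixel in the tests).
* `literal_eq2`: $\mathrm{ANPP} = \mathrm{NPP}/(1 + R/S)$ and
  $\mathrm{AGB} = \mathrm{ANPP}/[(R/S)(C_a + C_b)]$, the word-for-word
  alternative reading. It does not close the budget (and diverges as
  $R/S \to 0$), which is why it is not the default.

Per-type $R/S$, $C_a$, $C_b$ ship in `allocation_params()`; the two classes
without published rows (montane meadow, warm-temperate tussock) borrow the
nearest listed class and carry an explicit `proxy` flag. Carbon density of
AGB uses the conventional 0.45 coefficient.

Grazing intensity is the production/standing-crop balance
$\mathrm{GI} = (\mathrm{ANPP}_t - \mathrm{AGB}_t)/(P\,T)$ in livestock
units/m² (also reported per hectare). Negative balances have no livestock
interpretation and are floored at 0 with a flag. Defaults $P = 1800$ g
dry matter/day (a standard sheep unit) and $T = 365$ d are conventions, both
configurable. In the pipeline the consumed mass is taken as annual
production minus the peak-month standing crop: with a pure allocation model
annual production and annual standing biomass coincide by construction, so
the peak-month crop is the meaningful standing-crop term.

### Trend, stability and attribution statistics

Per pixel on annual series: the Theil–Sen slope (median of all pairwise
slopes; even counts average the two central order statistics) and the
Mann–Kendall test with tie-corrected variance and continuity correction,
using the normal approximation — appropriate for multi-decade series; the
exact permutation null is reserved for the test suite, where both statistics
are checked against exhaustive enumeration. Five trend classes combine a
stable band (|slope| < 0.5 g/m²/yr by default; the class thresholds are not
standardised in the literature, so the band is exposed) with significance at
α = 0.05. Stability uses the sample coefficient of variation, classified
into five levels at the 20/40/60/80th percentiles by default (fixed breaks
available).

Driver attribution has three views: per-pixel Pearson correlation with the
four-way SN/NSN/NSP/SP categorisation (an exact zero correlation, which the
strict inequalities leave unassigned, goes to NSP); per-type correlations of
spatially averaged series (a pooled pixel-year variant is available — the
spatial-mean default matches one summary number per type); and random-forest
relative importance of the seven drivers (T, PPT, VPD, SR, RH, SM, GI) via
`ranger` with 1000 trees and permutation importance on out-of-bag samples,
negatives floored at 0 and shares normalised to 100%. The default sampling
unit is one row per pixel (temporal means), switchable to pixel-years. With
a pure-noise response the raw permutation importances straddle zero, so the
normalised shares are unstable by construction; when every raw importance is
non-positive the shares fall back to uniform, and the honest null check is
on the raw scale (all importances near zero, no out-of-bag skill).

## The synthetic-scenario generator

`generate_scenario()` emulates the statistical structure the analysis
assumes, with exact bookkeeping so recovery can be scored:

* **NDVI**: per pixel, baseline + amplitude · sin² over an April–October
  growing season peaking in July (baseline 0.12, amplitude 0.50), plus
  Gaussian observation noise (sd 0.02), clipped to [−0.2, 1]. Gaps are a
  configured exact fraction of cells; spikes *replace* the observation with
  clip(factor × clean value), factor ×2 or ×0.2 — a sensor-artifact model
  that keeps the injected target unambiguous instead of riding on the
  observation noise. Gap and spike positions are recorded.
* **Meteorology**: seasonal cycles (temperature ±12 °C around 2 °C,
  summer-peaking precipitation and radiation), smooth spatial fields,
  per-pixel-year interannual anomalies, step noise, and configurable linear
  trends per variable.
* **Truth NPP**: the forward LUE model run on the noise-free fields — so
  preprocessing + model on the noisy inputs can be scored against it.
* **Truth AGB**: log-linear in the panel-standardised annual drivers
  (default effects GI 0.45 > SM 0.25 > PPT 0.15 ≫ T, VPD, SR, RH ≤ 0.05,
  mirroring the qualitative importance ordering reported for such systems),
  plus an optional linear ramp in g/m²/yr and Gaussian noise (sd 10 g/m²).
  The log-linear form keeps driver-recovery checks analytically tractable.

The generator does **not** emulate sensor physics, orbital drift,
calibration artefacts, spatially correlated observation noise, or
non-stationary seasonality. Passing recovery tests therefore demonstrates
the statistical machinery is correct and well-calibrated on data satisfying
its assumptions — not that real AVHRR-era archives satisfy them.

Determinism is a contract: the same configuration (including seed) yields
bit-identical scenarios, and `detail = "trend"` (which skips the expensive
forward-model truth for trend-only studies) draws the identical random
stream, so shared components agree exactly.

## Verification design and problem sizes

The test suite checks every statistic against an independent oracle:
Theil–Sen against brute-force pairwise enumeration (1000 random series,
n ≤ 12), Mann–Kendall against the exhaustive permutation null (all
orderings, n ≤ 7, including the textbook variance), Savitzky–Golay against
direct least-squares polynomial fits (including the edge rule), quantile
fences against hand computation, Pearson against the covariance formula,
and every closed-form model term against hand-evaluated values at 10⁻⁹.

Statistical recovery runs at deliberate desk scales: injected-trend
recovery (slope 1 g/m²/yr, noise sd 10 g/m²) on a 20 × 20 grid over 35
years, the false-positive rate of the Mann–Kendall test on 2025 pixels
under a null trend, spike/gap recovery on 35-year records, and
planted-driver recovery on 40 × 40 grids over 20 years at monthly cadence
(the larger domain matters: with spatially smooth driver fields the
effective sample size governs how quickly spurious pixel-mean correlations
of inert drivers shrink below the planted third-ranked effect). All sizes
were chosen so each property is measured with real statistical margin.

## Known limitations

* The LUE internals are standard-formulation defaults, not a calibrated
  regional configuration; absolute NPP/AGB levels from the demo pipeline
  are indicative, not validated against field plots.
* The per-type allocation parameters carry proxies for two classes.
* No pre-whitening or autocorrelation correction in the Mann–Kendall test;
  strongly autocorrelated residuals would inflate its false-positive rate.
* Sub-period comparisons (e.g. early vs late record) are run by invoking
  the pipeline on user-specified windows; there is no change-point
  estimation.
* File interchange is plain CSV/JSON rather than NetCDF/GeoTIFF; the long
  tibble format used throughout is the package's native container.
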