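# grassagb

Grassland aboveground biomass (AGB) is the basic field measure of grassland
condition, but multi-decade regional records can only be built by modelling:
estimate net primary productivity (NPP) from satellite greenness and
meteorology with a light-use-efficiency model, convert productivity to
standing biomass with per-type allocation parameters, and then characterise
the biomass record statistically. `grassagb` implements that full analysis
chain for researchers working with gridded NDVI + meteorological time
series, together with a synthetic-scenario generator with stored ground
truth so every stage is verifiable without any data download.

The core model is CASA-type light-use efficiency. Monthly, per pixel:

```
NPP(x,t) = APAR(x,t) × ε(x,t)
APAR     = SOL × FPAR(NDVI) × 0.5
ε        = Tε1(Topt) × Tε2(Topt, T) × Wε(PPT, PET) × εmax
```

with FPAR a clipped linear NDVI ramp, the two classic temperature-stress
terms, water stress `Wε = 0.5 + 0.5·E/Ep ∈ [0.5, 1]`, and
`εmax = 0.542 g C/MJ` for grassland by default. Production converts to
biomass per grassland type via root:shoot allocation,
`AGB = NPP / (Ca + (R/S)·Cb)` (the reading that closes the carbon budget
exactly; a literal alternative reading ships behind a strategy switch), and
carbon density is `0.45 × AGB`. Grazing intensity is the
production/standing-crop balance `GI = (ANPPt − AGBt)/(P·T)` in livestock
units per area. The statistics layer provides per-pixel Theil–Sen slopes,
Mann–Kendall tests (tie-corrected, continuity-corrected) with a five-class
trend map, coefficient-of-variation stability levels, four-way Pearson
correlation categories (SN/NSN/NSP/SP), per-type and seasonal correlation
tables, and random-forest driver importance (`ranger`, 1000 trees,
permutation importance normalised to percentage shares) for the seven
drivers T, PPT, VPD, SR, RH, SM and GI.

Everything is tidyverse-native: stacks are long tibbles
(`date, row, col, value`), every user-facing function takes a data frame
first and returns a tibble, results have `autoplot()`/`plot_*()` methods,
and the random-forest fit has `tidy()`/`glance()` methods.

## Worked example

Generate a 12 × 12, 10-year scenario, clean the NDVI, run the model chain
and look at the results:

```r
library(grassagb)

scen <- generate_scenario(synthetic_scenario(n_years = 10,
                                             grid_shape = c(12, 12), seed = 1))

pp <- preprocess_ndvi(scen$inputs$ndvi)   # fill -> screen -> refill -> smooth -> MVC
pp$report$n_filled
#> [1] 1728

npp <- casa_npp(pp$stack,
                temperature     = scen$inputs$temperature |> grassagb:::monthly_mean_stack(),
                solar_radiation = scen$inputs$solar_radiation |> grassagb:::monthly_sum_stack(),
                precipitation   = scen$inputs$precipitation |> grassagb:::monthly_sum_stack(),
                type_map = scen$inputs$type_map)
ann <- aggregate_period(npp$npp, "annual", "sum")
mean(ann$value)      # mean annual NPP, g C/m2/yr
#> [1] 442.4

agb <- npp_to_agb(grassagb:::annual_to_stack(ann, "g C/m2/yr", grid_geom(12, 12)),
                  scen$inputs$type_map)
mean(tibble::as_tibble(agb$agb)$value)   # mean annual AGB, g/m2
#> [1] 168.5
```

The mean AGB of ~170 g/m² sits in the range typical of temperate steppe
under the default (uncalibrated) model constants. Trend classification and
driver attribution:

```r
annual <- tibble::as_tibble(agb$agb)
annual$year <- lubridate::year(annual$date)
tr <- trend_analysis(annual[, c("year", "row", "col", "value")])
area_fraction(tr, "category")
#>   category                percent
#> 1 significant degradation    3.47
#> 2 slight degradation        26.4
#> 3 stable                    33.3
#> 4 slight improvement        34.0
#> 5 significant improvement    2.78

rf <- rf_importance(build_driver_table(scen$truth$driver_table),
                    n_trees = 1000, seed = 1, min_rows = 30)
rf
#> Random-forest driver importance (1000 trees, 144 rows, OOB R2 = 0.754)
#>   GI    68.14 %
#>   SM    14.66 %
#>   RH     8.60 %
#>   ...
```

With no injected trend the map is dominated by the stable/slight classes
(the five-class split of noise around zero slope), and the forest recovers
the generator's planted effect ordering: grazing intensity first, soil
moisture second. `autoplot(tr)` maps the five classes;
`plot_importance(rf)` draws the importance bars.

The whole chain also runs as one reproducible pipeline with a manifest:

```r
run <- run_pipeline(pipeline_config(output_dir = "run1", seed = 7))
```

or from a shell via `inst/scripts/agbpipe.R` (`--config`, `--seed`,
`--stages`, `--output-dir`). Re-running a configuration reproduces every
output byte for byte.

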