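# tomtrans

Daily transpiration modelling and irrigation evaluation for tomato grown
in coconut-coir substrate under a Venlo-type greenhouse.

Deficit irrigation of substrate-grown tomato trades yield against fruit
quality and water use efficiency (WUE). With the substrate film-wrapped,
a continuously weighed plant unit loses mass almost only by
transpiration, so the daily water balance of 08:00 weighing records

```
Td_i = W_i + I_i − R_i − W_{i+1}        (kg plant⁻¹)
Tm   = Td × PD                          (mm d⁻¹, PD = plants m⁻²)
```

gives daily transpiration directly. `tomtrans` implements the complete
analysis chain around that measurement:

* **water balance** — `daily_transpiration()`, `mass_to_depth()`,
  `wue()`, the deficit-trigger rule `irrigation_trigger()`;
* **crop state** — leaf area from length × width × 0.64, LAI, and
  shape-preserving daily interpolation (`interpolate_daily_lai()`, PCHIP);
* **driver screening** — Pearson correlation and path analysis
  (`path_analysis()`, direct coefficients solving `R_xx P = r_xy`,
  indirect effects `r_ij P_j`) of transpiration against solar radiation
  (DAR), vapour-pressure deficit (VPD), temperature (Ta), wind (W), LAI;
* **segmented model** — per-stage multivariate forms

  flowering/fruit setting: `Ts = a·DAR^b + c·ln VPD + d·ln Ta + e·ln LAI`

  picking: `Ts = a·DAR^b + c·exp(VPD) + d·ln Ta + e·ln W + f`

  fitted by Levenberg–Marquardt (`fit_stage_model()`), plus an
  unsegmented whole-season comparison model;
* **evaluation** — MAE, RMSE, MRE, Nash–Sutcliffe efficiency, R²
  (`compute_metrics()`, `compare_models()`);
* **treatment ranking** — TOPSIS over yield, WUE and quality indicators
  (`topsis()`, `entropy_weights()`), closeness `Ci = D⁻/(D⁺+D⁻)`;
* **synthetic data** — seeded generators for microclimate (mean-reverting
  AR(1) drivers with DAR–VPD–Ta coupling), logistic LAI, model-driven
  transpiration, and weighing records whose mass balance is exact bit for
  bit (`generate_*()`);
* **pipeline** — validated CSV schemas and `run_pipeline()` with
  subcommands `simulate`, `transpire`, `lai`, `screen`, `fit`, `predict`,
  `evaluate`, `rank`.

The treatment-level tables of the two-season experiment (growth indices,
fruit quality, yield/WUE, the published ranking) ship as plain-text
fixtures under `inst/extdata/`.

## Worked example

Percent changes of the deficit treatments against the wettest (T1), from
the packaged tables:

```r
library(tomtrans)
ch <- yield_wue_changes()
subset(ch, year == 2023 & pct_vs == "T1")
#>    year treatment        quantity pct_change pct_vs
#> 7  2023        T2 yield_per_plant     -13.08     T1
#> 8  2023        T2     yield_total     -10.90     T1
#> 9  2023        T2             wue      18.01     T1
#> 10 2023        T3 yield_per_plant     -26.15     T1
#> 11 2023        T3     yield_total     -24.38     T1
#> 12 2023        T3             wue      24.89     T1
```

The 70 % lower-limit treatment (T2) gives up ~11 % of total yield for an
18 % WUE gain. Ranking the treatments over all five indicators
(equal-weight, vector-normalized TOPSIS):

```r
topsis(indicator_matrix(2023))
#>   alternative d_plus d_minus    ci rank
#> 1          T1 0.0404  0.0345 0.461    3
#> 2          T2 0.0193  0.0372 0.659    1
#> 3          T3 0.0345  0.0404 0.539    2
```

T2 ranks first in both years — the deficit level that best balances
yield, quality and water use. Extracting transpiration from weighing
records:

```r
rec <- data.frame(date = 1:3, w_morning = c(52.40, 51.80, 51.30),
                  irrigation = c(1.50, 0, 0), return_flow = c(0.20, 0, 0))
daily_transpiration(rec, plant_density = default_plant_density())
#>   date td_mass flag tm_depth
#> 1    1     1.9   ok 9.047619
#> 2    2     0.5   ok 2.380952
```

`td_mass` is kg per plant-unit; `tm_depth` multiplies by the default
4.76 plants m⁻² of the wide/narrow-row layout. See the vignette
(`vignettes/transpiration-modelling.Rmd`) for the model forms, fitting
strategy, the identifiability caveat on the power-law pair, and what the
synthetic generator does and does not emulate.

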