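# ballastgwr

Where does mineral ballast matter for the *surface* export of particulate
organic carbon (POC)? Correlations between POC and mineral fluxes in the deep
ocean motivated "ballast effect" parameterisations in carbon-cycle models,
but the strength of the mineral–POC association in the upper ocean varies
regionally. `ballastgwr` is an R package for oceanographers working with
thorium-234-derived export fluxes: it decomposes surface POC export into
calcite- (PIC), opal- (BSi) and lithogenic-associated portions plus a
non-associated residual, and asks *where* each mineral carries POC by letting
the regression coefficients vary in space.

## The model

At each station the observed export fluxes (mg m⁻² d⁻¹) are related by

```
F_POC = a · F_PIC + b · F_BSi + c · F_lith + d + ε
```

where `a`, `b`, `c` are **carrying coefficients** (mg POC per mg mineral) and
`d` is the POC export not statistically associated with any mineral phase.
The package fits this twice:

* **MLRA** — one global ordinary-least-squares fit (`fit_mlra`).
* **GWR** — a geographically weighted regression (`fit_gwr`): at every
  station a weighted least-squares fit with an adaptive Gaussian kernel,
  `w_ij = exp(−½ (d_ij/h_i)²)`, where the local bandwidth `h_i` is the
  great-circle distance to the station's N-th nearest neighbour. The
  neighbour count N is selected by minimising the small-sample-corrected
  AIC (AICc), computed from the hat-matrix trace.

Model comparison and diagnostics follow the GWR literature: an ANOVA of the
GWR against the global fit (`anova_gwr_vs_mlra`), a test of geographical
variability that holds one coefficient global while the others stay local
(`test_geographical_variability`; a "Diff of Criterion" below −2 supports
genuine spatial variability), and residual Moran's I correlograms with
permutation significance (`residual_correlogram`). `partition_poc` then
converts the local coefficients into mineral-associated POC fluxes and
percent-ballasted shares, aggregated over ocean regions by
`regional_summary`.

Upstream of the regression, the `thflux` functions derive the fluxes
themselves: the ²³⁴Th/²³⁸U disequilibrium integrated to 100 m under the
one-dimensional steady-state model (`th_flux_steady_state`), element fluxes
via large-particle element:Th ratios (`element_flux`), and lithogenic flux
as 100/8 × the aluminium flux (`lithogenic_flux`).

Because the original 95-station observational table cannot be
redistributed, the package ships a first-class synthetic generator
(`generate_table`, `default_paperlike_config`) that draws station tables
with *known*, smoothly varying coefficient fields over Arctic, Atlantic and
Southern Ocean sampling boxes — so every stage is testable by parameter
recovery.

## Worked example

```r
library(ballastgwr)

gen <- generate_table(default_paperlike_config(seed = 42))
tab <- gen$table                    # a station_table, 95 stations

mlra <- fit_mlra(tab)
sel  <- select_bandwidth(tab)       # AICc bandwidth search
gwr  <- fit_gwr(tab, sel$kernel)
mlra; gwr
#> Global ballast regression (MLRA), n = 95
#>   a (PIC)  =   0.8381 mg C / mg PIC
#>   b (BSi)  =   0.1651 mg C / mg BSi
#>   c (lith) =   0.6246 mg C / mg lithogenic
#>   d (non-associated) = 80.32 mg m^-2 d^-1
#>   R^2 = 0.392   AICc = 1068.4   RSS = 3.719e+05
#> Geographically weighted ballast regression, n = 95
#>   bandwidth: 29 nearest neighbours (adaptive Gaussian)
#>   mean local coefficients: a = 0.820, b = 0.085, c = 0.458, d = 87.22
#>   R^2 = 0.550   AICc = 1050.8   tr(S) = 9.52
```

Letting the coefficients vary in space raises R² from 0.39 to 0.55 and
lowers AICc by ~18: spatial structure in the carrying coefficients is real
here (this table was generated with a PIC coefficient that steps up across
the equator). The ANOVA and the TGV agree:

```r
anova_gwr_vs_mlra(mlra, gwr)
#> GWR vs global MLRA: F(91, 85) = 5.45, p = 0.000129
test_geographical_variability(tab, sel$kernel)
#>       term coef_global diff_of_criterion converged
#>        pic  0.80959126             -3.38      TRUE
#>        bsi  0.07264242             -0.04      TRUE
#>       lith  0.13189875              0.84      TRUE
#>  intercept 81.92142911              2.76      TRUE
```

Only the PIC coefficient is flagged as spatially varying (Diff of Criterion
< −2), exactly the field the generator varied strongly; the constant
intercept comes out positive (no variability). Partitioning the export:

```r
part <- partition_poc(gwr, tab)
regional_summary(part)[, c("region", "n", "pct_ballasted")]
#>              region  n pct_ballasted
#> 1     nordic_arctic 12          34.0
#> 2              hlna 37         109.7
#> 3 subtropical_gyres 14          58.3
#> 4    southern_ocean 24          27.4
#> 5             other  8          40.8
#> 6            global 95          66.0
```

The high-latitude North Atlantic, where the generated PIC and BSi
coefficients are largest, is the most heavily ballasted region; the
Southern Ocean the least. (Station-mean percentages can exceed 100% when a
station's observed POC flux is small relative to its mineral-associated
terms — the per-station decomposition still sums exactly to the observed
flux, residual included.)

`run_full_analysis(tab, out_dir = "out")` performs all of the above plus
residual correlograms and writes each stage as CSV with a text summary.

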