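---
title: "Partitioning surface POC export over mineral ballast: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning surface POC export over mineral ballast: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ballastgwr)
```

## The scientific question

Sinking marine particles carry organic carbon out of the surface ocean. The
*ballast hypothesis* holds that dense biominerals — calcite (PIC), opal
(BSi) — and lithogenic dust either accelerate sinking or protect organic
matter from degradation, so mineral fluxes should statistically "carry" a
share of the particulate-organic-carbon (POC) flux. Whether that carrying
capacity is one global constant or varies between, say, the high-latitude
North Atlantic and the Southern Ocean matters for how carbon-cycle models
parameterise export. This package implements the analysis chain for testing
exactly that on ²³⁴Th-derived surface export data.

## From ²³⁴Th profiles to fluxes

²³⁸U is conservative in seawater (linear in salinity) while its daughter
²³⁴Th (half-life 24.1 d) is scavenged onto sinking particles, so an
upper-ocean deficit of ²³⁴Th relative to ²³⁸U integrates particle export
over the preceding weeks. Under the one-dimensional steady-state balance,

$$F_{\mathrm{Th}} = \lambda \int_0^{z} \bigl(A_U(z') - A_{Th}(z')\bigr)\,dz',$$

with $\lambda = \ln 2 / 24.1\ \mathrm{d^{-1}}$ and $z = 100$ m by default
(exposed as a parameter). `th_flux_steady_state` evaluates the integral by
the trapezoid rule — exact for the piecewise-linear profiles that discrete
bottle sampling implies — extends the profile to the surface by holding the
shallowest value, and permits locally negative deficits (²³⁴Th excess),
which subtract. Element fluxes follow from element:Th ratios of large
(>53 µm) particles pumped below the mixed layer; lithogenic flux is
$100/8 \times$ the Al flux, assuming 8 % Al in lithogenic material. The
²³⁸U–salinity law defaults to $0.0786\,S - 0.315$ dpm L⁻¹ and is fully
overridable, since several calibrations are in circulation; directly
measured ²³⁸U always takes precedence. BSi flux is reported as mg Si m⁻²
d⁻¹ (28.086 g mol⁻¹) without an opal-hydration mass correction — the
conservative convention, and one the carrying coefficients simply absorb.
Upwelling terms, non-steady-state Th models and uncertainty propagation are
out of scope.

## The ballast regression, global and local

The observation unit is a station (`station_table`) with POC, PIC, BSi and
lithogenic export fluxes in mg m⁻² d⁻¹. The model is

$$F_{POC} = a\,F_{PIC} + b\,F_{BSi} + c\,F_{lith} + d + \varepsilon,$$

where $a, b, c$ are carrying coefficients (mg POC per mg mineral) and $d$
is the non-associated POC export. `fit_mlra` is ordinary least squares via
`stats::lm`, with coefficients deliberately *unconstrained*: negative local
coefficients are scientifically meaningful (a mineral anti-correlated with
POC locally) and clipping them would bias every downstream summary.

`fit_gwr` re-fits the model at every station by weighted least squares,

$$\hat\beta_i = (X^\top W_i X)^{-1} X^\top W_i y,$$

with adaptive Gaussian weights $w_{ij} = \exp(-\tfrac12 (d_{ij}/h_i)^2)$,
where $d_{ij}$ is the haversine great-circle distance (sphere radius
6371 km — the stations span hemispheres, so degree-space metrics would
distort high-latitude neighbourhoods) and $h_i$ is the distance to the
$N$-th nearest neighbour of station $i$ (the station itself counted as
neighbour 1). The target keeps weight 1 in its own fit; overfitting is
controlled through the effective parameter count rather than by
leave-one-out. Distance ties (co-located stations) simply share the same
$h_i$; if the whole neighbour set is co-located the bandwidth degenerates
to zero and the fit aborts with a remediation hint rather than returning
infinite weights.

### Effective parameters and AICc

Each local fit contributes a hat-matrix row
$r_i = x_i^\top (X^\top W_i X)^{-1} X^\top W_i$; the effective number of
parameters is $\mathrm{tr}(S) = \sum_i r_{i,i}$, which runs from $p = 4$
(uniform weights) toward $n$ (very local fits). Model scoring uses the
small-sample Gaussian AICc of the GWR literature,

$$\mathrm{AICc} = 2n\ln\hat\sigma + n\ln 2\pi +
  n\,\frac{n + k}{n - 2 - k}, \qquad \hat\sigma = \sqrt{RSS/n},$$

with $k = \mathrm{tr}(S)$ for the local model and $k = p + 1$ for the
global one (the extra unit for the estimated error variance). The two
conventions differ by roughly one effective parameter; we keep them as
stated so the global and local scores live on one comparable scale, and
treat the *ordering* of AICc values, not their second decimal, as the firm
claim.

`select_bandwidth` minimises AICc over integer neighbour counts with a
golden-section search followed by an exhaustive sweep of the final bracket
(profiles are near-unimodal but integer-valued and mildly noisy; the sweep
removes any sensitivity to the bracketing path). Ties break toward the
larger, smoother bandwidth. The default search range is $[p + 2, n]$.

### Test of geographical variability

For each term $k$, `test_geographical_variability` fits a semiparametric
model in which that coefficient is global while the other three stay
local. The global coefficient is estimated by two-stage back-fitting:
with $S$ the GWR smoother built on the reduced (three-column) design,
iterate

1. $f \leftarrow S\,(y - x_k b)$ (local part),
2. $b \leftarrow \langle x_k,\, y - f\rangle / \langle x_k, x_k\rangle$,

to convergence of $b$ (relative tolerance $10^{-6}$, at most 100
iterations; non-convergence is flagged per term, never silently ignored).
The fixed point is $b = [x_k^\top(I-S)x_k]^{-1}x_k^\top(I-S)y$, and the
mixed model's hat matrix is $L = S + (I-S)x_k m$, whose trace
$\mathrm{tr}(S) + x_k^\top(I-S)^\top(I-S)x_k / x_k^\top(I-S)x_k$ we use
exactly (the commonly quoted "+1" is only approximate). The **Diff of
Criterion** is AICc(fully local) − AICc(term-$k$ global): below −2 supports
genuine spatial variability of the term, within ±2 is weak evidence, and
positive values favour the global term. We also evaluated the
doubly-smoothed least-squares profile estimator for $b$; in calibration
simulations it inflated the false-flag rate of the intercept term, so the
simpler moment-form update above is the shipped estimator. Under
constant-coefficient truth the per-term false-flag rate at the −2
threshold is 4–8 % in our calibration runs — AICc differences between
non-nested smoothers genuinely fluctuate by a couple of units, so −2
should be read as "weak evidence" exactly as the threshold convention
says, not as a 5 % test.

### ANOVA

`anova_gwr_vs_mlra` uses the GWR-ANOVA convention
$F = [(RSS_{glob} - RSS_{gwr})/\nu_1] \,/\, [RSS_{gwr}/\nu_2]$ with
$\nu_1 = \mathrm{tr}(S) - p$ and $\nu_2 = n - \mathrm{tr}(S)$, reporting
the conventional display degrees of freedom $(n - p,\ \mathrm{round}(n -
\mathrm{tr}(S)))$ while computing the p-value from the real-valued
$(\nu_1, \nu_2)$. If the GWR fails to improve on the global fit (possible
only away from the AICc-optimal bandwidth), F is reported as 0 with a
warning rather than as a negative number.

## Residual correlograms

A well-specified spatial model leaves no residual autocorrelation at any
scale. `residual_correlogram` computes binary-weight Moran's I per distance
bin with two-sided permutation p-values (residuals relabelled across
stations; the seed is recorded in the output). Bins default to ten
equal-count (quantile) distance bins because station density is very
uneven across basins; permutation inference is used because per-bin pair
counts are small and the weights binary. One caution for readers of the
paired MLRA/GWR correlograms: with ten bins at $\alpha = 0.05$, even
perfectly whitened residuals show a falsely significant bin in roughly a
third of tables, so the meaningful comparison is whether the bins flagged
under the global fit *lose* significance under the GWR — which is how the
package's tests phrase it — not whether the GWR correlogram is entirely
blank.

## Partitioning the export

`partition_poc` turns coefficients into fluxes: $POC_{X,i} =
\hat\beta_{X,i} F_{X,i}$ per mineral, $POC_{nonassoc,i} = \hat d_i$, and
percentages are taken relative to the *observed* POC flux. The observed
denominator keeps "percent of export ballasted" anchored to what was
measured; exact additivity is preserved by carrying the residual
explicitly, so at every station

$$POC_{pic} + POC_{bsi} + POC_{lith} + POC_{nonassoc} + \text{residual}
  = F_{POC}$$

to machine precision (a tested invariant). Negative components are
reported as-is and flagged (`clip_negative = TRUE` exists but breaks the
invariant and is off by default). Stations with very small observed POC
flux produce arbitrarily large percentages — station-mean percentages can
therefore exceed 100 %, which is a property of the estimator, not a bug;
`regional_summary(..., flux_weighted = TRUE)` provides the stabler
flux-weighted alternative, while the unweighted station mean remains the
headline because the averaging convention of the original analysis is not
recorded. Default regions are latitude/longitude boxes (Nordic/Arctic
≥ 66.5°N; high-latitude North Atlantic 45–66.5°N in the Atlantic sector;
subtropical gyres |lat| < 25°; Southern Ocean ≤ 45°S), matched in priority
order with unmatched stations reported under "other"; the province
polygons of the original study are not printed anywhere, so boxes are the
honest reproducible choice and are user-overridable.

## The synthetic generator: what it emulates and what it does not

`generate_table` draws station tables satisfying the ballast model
*exactly*: uniform station placement within per-basin boxes, lognormal
mineral fluxes (export fluxes are positive and right-skewed), true
coefficient fields evaluated per station, Gaussian noise, and rejection
re-draws of the noise for stations whose POC flux would go negative — so
the linear model remains exactly true for every retained station, which is
what makes closed-loop recovery tests meaningful.

`default_paperlike_config` encodes the study conditions this package was
built around: 95 stations, 49 north of 45°N and 24 south of 45°S across
Nordic/Arctic, high-latitude North Atlantic, Atlantic gyre and Southern
Ocean boxes. The coefficient fields follow the fitted spatial patterns of
the original surface-export analysis: the PIC coefficient steps up across
the equator (logistic, −0.25 south to 0.97 north, 15° width), giving a
station-weighted mean of ~0.57 and a range of ~1.2 under the north-heavy
sampling; the BSi coefficient is a weaker step (0.06 to 0.33 around a mean
of ~0.26); the lithogenic coefficient trends very weakly northward around
0.10; and the non-associated intercept is constant at 89 mg m⁻² d⁻¹ — the
variability test of the original analysis found no spatial structure in
the intercept, so its mapped variation is treated as estimation noise.
The noise standard deviation (60 mg m⁻² d⁻¹) and PIC flux scale were set
once, at design time, so that the global-fit R² of generated tables sits
near the reported 0.22 while the geographically weighted fit reaches
roughly 0.5; individual seeds scatter substantially around those means,
which is why the package's tests assert orderings and sign patterns rather
than point values on synthetic tables.

What the generator does **not** emulate: ²³⁴Th measurement error and its
propagation into the fluxes, seasonal aliasing of the Th method,
spatially structured mineral-flux fields (fluxes are i.i.d. lognormal, so
regional flux contrasts — e.g. Southern Ocean opal dominance — are absent),
and correlated mineral phases. Passing recovery tests therefore
demonstrates that the estimators are correct under the model's own
assumptions, not that real export data satisfy them.

## Numerical choices and problem sizes

Degenerate inputs fail loudly: rank-deficient designs name the collinear
columns, co-located neighbour sets name the station and suggest jitter,
AICc refuses $n \le k + 2$, and empty or zero-variance correlogram bins
are flagged rather than computed. All simulation-based tests fix their
seeds and use deliberately modest problem sizes — tables of 40–95 stations,
50-replicate calibration loops, 199–999 permutations — chosen as the
smallest sizes at which the statistical claims under test are stable.

## Known limitations

* The exact Gaussian kernel constant and the mixed-model estimator inside
  the original GWR software are unpublished; reproduced AICc values and
  Diffs of Criterion can differ in the decimals, so orderings and signs are
  the claims this package stands behind.
* Only the adaptive Gaussian kernel is implemented — no bisquare or
  fixed-distance bandwidths, no multiscale GWR, and no Monte-Carlo test of
  the coefficient surfaces.
* The Th-flux module implements the steady-state balance only.
* Station-mean percentage summaries are sensitive to small-POC stations,
  as discussed above.
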