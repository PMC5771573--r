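---
title: "Methods: wind-driven upwelling and summer bloom analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wind-driven upwelling and summer bloom analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the physical model, the statistical machinery, the choices made where the
problem is genuinely open, and what the synthetic validation does and does
not demonstrate.

## The physical model

Summer monsoon winds over a coastal sea force upwelling through two
pathways. Away from the coast, a spatially varying wind stress produces
divergent Ekman drift; mass conservation requires a vertical velocity at
the base of the Ekman layer,

$$\mathrm{EPV} = \frac{\nabla\times\tau}{\rho f} + \frac{\beta\,\tau_x}{\rho f^2},$$

positive upward. At the coast, the stress component parallel to the
coastline, $\tau_c$, drives offshore surface transport

$$\mathrm{ET} = \frac{\tau_c}{\rho f}$$

(m² s⁻¹ per unit coastline length), compensated by coastal upwelling.
Upwelled water is colder and nutrient-richer than the surface water it
replaces, so strong upwelling appears as an SST drop and, with a delay of
days (phytoplankton growth plus the shoaling of the subsurface chlorophyll
maximum), a chlorophyll-a increase.

Stress comes from 10-m winds through the bulk formula
$\tau = \rho_{air} C_d |U| (u, v)$ with a constant $C_d = 1.3\times10^{-3}$
by default. A constant coefficient keeps every test oracle analytic; the
piecewise Large & Pond (1981) neutral coefficient is available via
`cd_scheme = "large_pond"` for realism at high wind speeds.

Choices inside the dynamics:

- **Per-cell Coriolis parameters.** $f$ and $\beta$ are evaluated at each
  cell's latitude rather than a fixed central latitude; the pointwise
  formula is the natural reading and costs nothing.
- **β term off by default.** In the 10–14°N band with stresses up to
  0.2 N m⁻² and 500-km curl scales, the β term stays below 10 % of the
  curl term (`beta_term_ratio()` measures ≈ 0.07). It is implemented and
  flag-switchable precisely so that neglect is checkable, not assumed.
- **Spherical-metric differencing.** The curl uses central differences
  with $\partial/\partial x = (R\cos\varphi)^{-1}\partial/\partial\lambda$
  and $\partial/\partial y = R^{-1}\partial/\partial\varphi$. Domain-edge
  cells are masked by default (one-sided differences are available); cells
  whose stencil touches missing data are masked, because a central
  difference across a land cell is not meaningful. Truncation error is
  second order, verified by factor-2 refinement.
- **Equatorial guard.** $|{\rm lat}| < 1°$ is masked with a warning since
  $f^{-1}$ and $f^{-2}$ diverge; the study domain (8–22°N) is unaffected.
- **Coastline as a supplied bearing.** The coastline tangent (default 35°
  clockwise from north, a good straight-line fit to the southeast Vietnam
  coast) is an explicit input, optionally a per-latitude table, rather
  than something inferred from a land mask. Positive ET is
  upwelling-favorable (offshore) for a coast with the ocean on the right
  of the bearing. The sign convention is ours and documented, not
  inferred from any particular study.

## Gridded data handling

All fields are `(time, lat, lon)` arrays with units and NA masks;
coordinates are cell centers, normalized to ascending order, longitudes to
(−180°, 180°]. Cross-variable work happens on a common grid — when mixed
resolutions are ingested, everything is regridded bilinearly to the wind
grid, since EPV/ET live there and interpolating the coarser field avoids
inventing fine-scale chlorophyll structure. The bilinear rule is
conservative about missing data: a target cell whose 4-point stencil
touches any masked source cell is masked, even at zero weight. Box
membership is by cell-center inclusion in a closed box.

Composites are per-cell means over unmasked samples with per-cell counts
recorded. The six summer fifteen-day windows are Jun 1–15, Jun 16–30,
Jul 1–15, Jul 16–31, Aug 1–15, Aug 16–31: the two late windows hold 16
days, because tiling the season completely beats literal fifteen-day
equality. Box-averaged series use cos(latitude) area weighting by default
(a flag disables it); whether published box series in this literature were
area-weighted is typically unstated, and at these box sizes the difference
is far below the noise.

Missing data policy: pairwise deletion for correlations (a day missing in
either series is dropped for that pair), listwise-by-cell for EOFs (a cell
with any missing time step is excluded and reported). Both are the
simplest defensible treatments for cloud-gapped ocean-color data.

## EOF decomposition

Anomalies (per-cell time mean or calendar climatology removed) are
arranged as a cells × time matrix $X$ and decomposed as $X = LY$ with
orthonormal spatial modes $L$ and amplitude-carrying principal components
$Y$, via the eigenstructure of whichever of $XX^\top$ or $X^\top X$ is
smaller — mathematically the SVD, and the test suite holds it to an
independent `svd()` oracle at 1e-8. Variance fractions are
$100\,\lambda_k/\sum\lambda$. Numerical conventions: modes are ordered by
decreasing variance; rank is cut at $10^{-12}\lambda_1$; requesting more
modes than rank truncates with a warning; each spatial mode's
largest-magnitude element is made positive (EOF signs are arbitrary, so a
convention is fixed and the PC absorbs the flip; ties resolve to the first
such element). The covariance (not correlation) matrix is decomposed, and
no area weighting is applied by default (√cos lat is a flag) — the
analysis boxes are latitudinally narrow.

In the pipeline the EOFs are computed on **monthly composites**: daily
chlorophyll with realistic cloud gaps leaves no cell with a complete daily
record, while monthly means average the gaps out. The pipeline retains one
mode by default — in strongly monsoon-forced regions the leading mode
carries most of the variance — but the decomposition computes any
requested number.

## Correlation machinery

For predictors $x_1,\dots,x_m$ (here SST, ET, EPV) and response $y$
(Chl-a), the joint correlation matrix $R$ yields the multiple correlation
and partial correlations through its determinant and signed cofactors
$C_{ij}$:

$$R_{y\cdot1..m} = \sqrt{1 - |R|/C_{yy}}, \qquad
  R_{yi\cdot} = -\,C_{yi}/\sqrt{C_{yy}C_{ii}}.$$

These are the classical textbook identities; the suite verifies them
against ordinary-least-squares $\sqrt{R^2}$ and residual-correlation
oracles to 1e-10 on random tables. Significance: two-sided $t$ with
$n-2$ (simple) or $n-m-1$ (partial) degrees of freedom and the $F$ test
for the multiple correlation; an `effective_n` option deflates the sample
size by $n(1-\rho_1\rho_2)/(1+\rho_1\rho_2)$ using lag-1 autocorrelations,
a standard heuristic for serially correlated daily geophysical series
(which the default $t$ test treats as independent — p-values on daily
summer series should be read with that in mind). Predictor ordering in
$R$ is fixed as (SST, ET, EPV, Chl-a) so cofactor indexing is
reproducible. Degenerate inputs error early: zero-variance series are
named, exact collinearity among predictors is reported as such, $|r|=1$
yields $p=0$ flagged degenerate.

Whether a correlation analysis of this kind should pool daily summer
series across years or use one summer mean per year is a genuine
ambiguity; both run through the same code path here (the series table is
agnostic), and the default workflow uses the pooled daily series of the
simulated season.

## The synthetic generator

`synthetic_config()` defines the study conditions; its defaults are fixed
once and the tests run against them:

- **Grid and season**: 0.125°, 106–116°E, 8–22°N; 1 Jun–31 Aug of a
  single case-study year. One season suffices for the recovery
  experiments; multi-year runs (for climatology and anomaly baselines)
  are configuration, not new code.
- **Wind** (6 m s⁻¹ background, bearing 40°): a coast-parallel jet —
  speed multiplied by $0.6 + 0.8\exp(-((d-350)/200)^2)$ with $d$ the
  offshore distance in km — so the stress has both curl (EPV) and a
  coast-parallel component (ET). An abrupt intensification adds 4 m s⁻¹
  from Jul 25 over a 10-day half-cosine ramp, emulating an
  observed-in-nature late-July monsoon surge. Deterministic sinusoidal
  modulations of bearing (±8°, 30-day period) and jet position (±60 km,
  45-day period) stand in for intraseasonal (MJO-like) variability and
  keep the EPV and ET box series from being perfectly collinear. These
  modulations are part of the closed-form skeleton: with noise set to
  zero the wind is exactly reproducible by hand, which is what the unit
  tests do.
- **Coupling**: SST = 29.5 °C + (−0.05 °C m⁻¹) × (15-day running integral
  of EPV) — upwelling cools cumulatively, and the window matches the
  compositing granularity. Chl-a = 0.1 mg m⁻³ + 10⁴ (mg m⁻³)/(m s⁻¹) ×
  EPV(t−3 d) + 0.01 (mg m⁻³)/(m² s⁻¹) × ET(t−3 d), floored at
  0.01 mg m⁻³. The gains put EPV clearly ahead of ET in explanatory
  power, give box chlorophyll in the 0.15–0.5 mg m⁻³ range and an SST
  decline of ~1–2 °C over the event — the magnitudes a field scientist
  would call realistic for this regime. The forcing driving the
  responses is the noise-free EPV/ET computed by the package's own
  Ekman code, so the generator exercises the same operators the analysis
  uses.
- **Noise and masks**: Gaussian noise (1 m s⁻¹ per wind component,
  0.2 °C, 0.03 mg m⁻³); chlorophyll log-normality is available as a flag
  but off by default so the correlation truth stays linear. Land is
  masked northwest of the idealized coastline through (108.5°E, 11.5°N)
  at bearing 35°; chlorophyll cell-days are cloud-masked i.i.d. with
  probability 0.2 — real clouds are spatially correlated, which is out
  of scope and means the generator is kinder to gap-handling code than
  nature is.

What passing the recovery experiments shows: the pipeline's plumbing is
sign- and magnitude-correct end to end, and the correlation machinery
ranks a built-in dominant driver above a secondary one. What it does not
show: anything about retrieval error, correlated cloud gaps, ecosystem
dynamics (the chlorophyll response is linear by construction, with no
nutrient or grazing model), or the attribution of any real-world bloom.

## Validation problem sizes

The test suite and the acceptance script size their experiments as
follows, chosen to make the statistical checks meaningful while keeping a
full run comfortable on a laptop: the analytic Ekman benchmark on the full
0.125° band (≈ 2 500 interior cells, error ≈ 0.5 % RMS against a 1 %
bound); 100 random series tables for the cofactor-vs-regression
equivalence; 1 000 white-noise pairs of length 90 for the type-I error of
the $t$ test (nominal 0.05 ± 0.02); 50 random 20 × 30 matrices against
the SVD oracle; 20 seeds each for the 80/15/5 variance-share recovery,
the full-pipeline sign recovery, and the paired event-vs-control
contrast.

## Known limitations

- No Ekman-layer depth or spiral model, no geostrophic currents, no
  ENSO/MJO indices: the scope is the wind-to-bloom diagnostic chain.
- The constant-$C_d$ bulk formula underestimates stress above ~11 m s⁻¹;
  switch to `"large_pond"` when absolute magnitudes matter.
- EOF mode separation significance (North's rule), rotated and complex
  EOFs, and lagged cross-correlation analysis are deliberate
  non-features; they would be natural extensions.
- NetCDF time units support is `seconds/hours/days since <date>`, daily
  resolution; sub-daily data are not handled.
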