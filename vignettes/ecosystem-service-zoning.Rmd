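---
title: "Methods: ecosystem-service importance assessment and zoning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ecosystem-service importance assessment and zoning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecozoner)
```

`ecozoner` scores every cell of an aligned raster landscape on four
ecosystem services — habitat quality, carbon storage, annual water yield,
and soil retention — then combines them with entropy weights into one
importance score and a four-tier natural-breaks zoning. This vignette is
the package's own account of the models, their assumptions, the parameters
that matter, and the design decisions taken where the methodology was
genuinely open.

## The raster data model

A layer is an `eco_grid`: a numeric matrix (row 1 = northern edge), a
square cell size in metres, and a lower-left origin; `NA` is nodata. The
package validates alignment (`assert_aligned()`, tolerance 1e-6 on cell
size and origin) but deliberately never resamples or reprojects: blending a
resampling policy into a model core makes results depend on an invisible
cartographic choice, so mixed-resolution inputs must be brought to a common
grid upstream. Any stage output is nodata wherever any required input is
nodata — no value is ever fabricated under a mask. I/O uses the ESRI ASCII
grid text format, written with 17 significant digits so doubles round-trip
exactly; this is what makes a rerun of the same configuration and seed
byte-identical, a property the test suite asserts.

## Habitat quality

Threats are land-use-derived stressors (cropland, built land, roads,
settlements), each with a weight $W_r \in (0,1]$, a maximum impact distance
$d_{max}$, and a decay shape. Influence at distance $d$ from the *nearest*
source cell is

$$i(d) = \max(0, 1 - d/d_{max}) \quad\text{or}\quad
  i(d) = e^{-(2.99/d_{max})\,d}\ \ (0\ \text{beyond}\ d_{max}),$$

the exponential constant chosen so influence is ~5 % at the maximum impact
distance. Degradation and quality per cell $x$ in land-use class $j$:

$$D_x = \sum_r \frac{W_r}{\sum_r W_r}\, i_r(x)\, \beta_x\, S_{jr},
\qquad
Q_x = H_j\left(1 - \frac{D_x^z}{D_x^z + k^z}\right).$$

Assumptions and choices:

* **Nearest-source influence.** Summing decayed influence over *every*
  source cell makes $D$ grow without bound with source area and cannot stay
  in a bounded range; the nearest-source reading keeps $i_r \in [0,1]$ and
  is the established practice for this model family. Degradation therefore
  responds to proximity, not to source density.
* **Half-saturation $k$** (default 0.5, configurable): the degradation
  level at which quality halves. With normalised weights and sensitivities
  in $[0,1]$, $D$ in practice lives well below 1, and $k = 0.5$ places the
  half-response in the middle of that working range. $z = 2.5$ is the
  conventional sharpness exponent.
* **Accessibility $\beta_x$** defaults to 1 (no accessibility layer is
  required); supply a grid in $[0,1]$ to damp threat exposure, e.g. inside
  fenced reserves.
* Threats with no source cells on a map contribute zero but stay in the
  weight normalisation, which is what makes $D$ exactly invariant to
  rescaling all weights by a common factor (property-tested).
* Distance fields are exact Euclidean distance transforms (centre to
  centre), computed by `EBImage::distmap()` behind `distance_field()` and
  verified against brute-force nearest-source search in the tests.

## Carbon storage

Carbon is a pure bookkeeping model: per secondary land-use class, densities
of four pools (aboveground, belowground, soil, dead organic matter, t/ha)
are summed and multiplied by cell area. The packaged density table has
all-zero rows for built classes; it also carries a zero-density `bare_land`
row so maps with unused land run — the published parameterisations this
table mirrors do not list an unused-land class, and zero is the
conservative stand-in for barren ground. Carbon is the one module keyed by
the *secondary* legend (densities differ between, say, dense woodland and
shrubland); all other tables are keyed by the six primary classes, and the
land-use code table is the single place that reconciles the two legends.

## Water yield

On vegetated classes (arable, woodland, grassland) the Budyko curve
partitions rainfall:

$$\frac{AET}{P} = 1 + \frac{PET}{P} -
  \left(1 + \left(\tfrac{PET}{P}\right)^{\omega}\right)^{1/\omega},
\qquad \omega = \frac{Z \cdot AWC}{P} + 1.25,$$

with $PET = K_c \cdot ET_0$. On non-vegetated classes (waters,
construction, unused) $AET = \min(K_c ET_0, P)$. Yield is $Y = P - AET$,
reported as water conservation in mm/yr.

* **Seasonality constant $Z$** (dimensionless, validated to $[1, 30]$) has
  no universal value; synthetic runs use $Z = 10$, a mid-range value typical
  of monsoon-influenced catchments. Yield decreases as $Z$ rises
  (property-tested), so $Z$ should be calibrated against gauged runoff when
  real data are available.
* The curve is evaluated in the scale-stable form
  $(1+x^\omega)^{1/\omega} = m\,(m^{-\omega} + (x/m)^\omega)^{1/\omega}$
  with $m = \max(x, 1)$, so large dryness ratios and large $\omega$ do not
  overflow; the result is clamped to $[0,1]$ against last-ulp roundoff.
* A numerical subtlety worth recording: the large-$\omega$ limit of the
  fraction is $\min(PET/P, 1)$, but convergence is *non-uniform* at
  $PET/P = 1$, where the exact value is $2 - 2^{1/\omega}$ (≈ 0.014 above
  the limit at $\omega = 50$). Tests check the limit band away from that
  point and pin the closed form at it.
* Cells with $P = 0$ get nodata $\omega$ (the ratio is undefined) with a
  warned count. AWC is consumed directly as a grid in mm; root depth is
  carried in the biophysical table for provenance but enters only through
  AWC.

## Soil retention

Monthly rainfall erosivity
$R = \sum_{i=1}^{12} 1.735 \cdot 10^{1.5\log_{10}(p_i^2/P) - 0.8188}$,
multiplied by 17.02 (a config flag, default on, recorded on the output) to
reach SI units. Zero-rain months contribute nothing; zero-rain cells get
$R = 0$ — no rain, no erosive power.

EPIC erodibility uses the Williams four-factor form with the first-factor
coefficient $-0.0256\,SAN$ (SAN in percent). The frequently reprinted
variant $-0.256$ collapses the factor to 0.2 for every realistic sand
content and erases the texture signal entirely, so the original coefficient
is the default (it is an argument, so the variant can be reproduced
deliberately). $K$ is strictly decreasing in organic carbon over the
agronomic range — a directional check in the tests.

No closed LS recipe is universal, so the package documents its own: Horn
3×3 finite-difference slope (edge rows/columns replicate, so single-row
strips stay well-defined), D8 steepest-descent flow accumulation in cells
(each cell counts itself; ties and pits simply stop routing), slope length
$\lambda = \min(A \cdot \text{cellsize}, 333\,\text{m})$, and

$$LS = (\lambda / 22.13)^{0.4} \cdot (\sin\theta / 0.0896)^{1.3}.$$

22.13 m and 0.0896 are the USLE unit-plot length and slope, so a
single-cell flow path of 22.13 m at the reference gradient has $LS = 1$
exactly (anchored in the tests). The 333 m cap is the standard guard
against runaway slope lengths on long smooth hillsides.

The stack is then $USLE = R\,K\,LS\,C\,P$ (actual loss),
$RKLS = R\,K\,LS$ (bare-soil potential loss), and retention
$SD = RKLS - USLE = RKLS\,(1 - CP) \ge 0$ because $C, P \in [0,1]$. Waters
and construction carry $C = P = 0$ (no loss, full retention of the
potential), unused land $C = P = 1$ (zero retention) — the behaviour the
tests pin per class. Totals in tonnes multiply loss rates by cell area in
ha.

## Entropy weighting and zoning

The four service layers are stacked over cells valid in all layers and
min–max normalised (all four are benefit-oriented: more service, more
importance). With $n$ cells and normalised values $p_{ij}$,

$$f_{ij} = \frac{p_{ij}}{\sum_j p_{ij}}, \qquad
H_i = -\frac{1}{\ln n}\sum_j f_{ij}\ln f_{ij}, \qquad
W_i = \frac{1 - H_i}{m - \sum_i H_i},$$

with $0\ln 0 := 0$. $1/\ln n$ is the unique normalisation putting
$H_i \in [0,1]$. Weights are computed from the full cell-level matrix, not
from class summaries — the dispersion that drives the weights lives at the
cell scale. A constant normalised column is set to 0.5 and flagged: it
carries no ranking information, and the declared convention (entropy → 1,
weight → 0) beats a silent 0/0. The importance score is the weighted sum,
in $[0,1]$.

Tiers come from exact Fisher–Jenks natural breaks (dynamic programming in
C++, $O(kn^2)$), verified against exhaustive search over all break
placements for $n \le 20$ in the tests. Above `sample_cap` values (default
6000) the breaks are fitted on evenly spaced order statistics of the sorted
scores and then applied to all cells — the standard map-scale practice; the
thinning is deterministic, so reproducibility is untouched. Ascending score
maps to the labels general → moderate → high → extreme, and per-tier areas
(km² and percent of the valid area) complete the result.

## The synthetic landscape

`generate_landscape()` exists so that every stage, and the end-to-end
zoning, runs offline and reproducibly. It emulates the conditions of a
woodland-dominated mountain protected area: target class fractions
(woodland 0.70, grassland 0.12, arable 0.10, construction 0.04, waters and
unused 0.02 each), elevation spanning 808–3748 m exactly, annual rainfall
around 900 ± 150 mm/yr positively correlated with elevation, a fixed
unimodal monsoon monthly profile (July–August ≈ a third of the annual
total), reference evapotranspiration declining ~30 % from valley to summit,
and soil texture fields that always sum to 100 %. Random fields are
Gaussian-smoothed seeded white noise (smoothing radius `smooth_sigma`, 8
cells by default — patch diameters of a few hundred metres at 30 m
resolution); land use is carved from a smooth "naturalness" surface by
quantile slices, which makes realised fractions match targets to within a
cell and keeps classes spatially contiguous. The generator restores the
caller's RNG state, and identical seeds give bit-identical bundles.

What it does *not* emulate: real geostatistics (no variogram fitting),
valley-following hydrography, road networks that follow terrain, or the
spatial covariance between soil and vegetation. Tests passing on synthetic
landscapes therefore demonstrate correctness of the *computations* and the
pipeline's invariants — not calibration of any real region. The worked
1×N strip (`worked_strip()`) is the opposite extreme: small enough that
every stage is hand-checkable cell by cell, and the suite does exactly
that.

## Problem sizes and runtime

The default test and acceptance runs use 200 × 200 cells (36 km² at 30 m),
the size at which a full `run_pipeline(..., "all")` — four services,
weighting, zoning, all artifacts written — completes in a few seconds on a
single core. The models are linear in cell count except Jenks (handled by
the sampling cap) and the distance transforms (near-linear); the pipeline
has been sized so a practitioner can iterate interactively.

## Known limitations

* No resampling/reprojection: inputs must be pre-aligned.
* GeoTIFF is not read directly; convert to ESRI ASCII grid first.
* Habitat degradation reacts to the nearest source only, not source
  density; rarity weighting and time-varying threats are out of scope.
* Water yield is an annual lumped balance — no monthly routing, no
  consumptive-use netting.
* Soil retention has no sediment-delivery ratio; totals are gross
  on-cell quantities, not catchment export.
* Entropy weights are relative to the landscape at hand: adding or
  removing area changes the dispersion of every indicator and hence the
  weights. That is inherent to objective weighting, not a defect, but it
  means scores are comparable within one run, not across regions.
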