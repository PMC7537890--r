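---
title: "Disassembling a neural surrogate of ecosystem service value"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disassembling a neural surrogate of ecosystem service value}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esvdriver)
```

## The problem and the model

Ecosystem service value (ESV) summarises, in currency per area, the benefit
flow a landscape provides. Under the equivalent-factor convention each
land-use class has a value density, so a grid cell's ESV is the sum of
class area times class coefficient. ESV is, however, shaped indirectly by
socioeconomic conditions — industry structure, energy and water use,
population pressure — and the relationship is nonlinear and interactive.
`esvdriver` treats it as a supervised learning problem: fit a multilayer
perceptron (MLP) mapping 23 standardized socioeconomic factors to ESV per
grid unit, then *disassemble* the fitted network rather than treat it as a
black box:

* **single-factor response curves** — sweep one factor over its sampling
  domain with every other factor held at its sample mean; the width of the
  traced ESV interval (the response-domain range) measures influence
  intensity, the curve's trend its influence mode;
* **two-factor coupling surfaces** — the same construction on a 2-D grid,
  exposing interactions and the factor combination maximizing ESV;
* **synergistic features** — with a linear scalar output layer, predictions
  are exactly `sum_j w_j h_j + b` over the penultimate ReLU activations
  `h_j`, so each penultimate neuron is an interpretable multi-factor
  feature whose factor content can be quantified and compared with PCA
  components.

## Data model and spatial fusion

The analysis consumes 1 km rasters (ESV, GDP, population, nighttime light
index, NDVI, land-use class areas with construction split into industrial
and residential) plus a table of 13 city-level statistical totals: industry
outputs A4–A8 and electricity/water consumption C1–C8. Totals are spread
over the grid by dasymetric allocation against an ancillary weighting
layer — cultivated land for agriculture-linked indicators, industrial /
residential / construction land for the corresponding industry and
consumption indicators, the light index for tourism, population for total
electricity and water. Allocation is proportional, so each indicator's grid
sum reproduces its city total to machine precision; this conservation is
asserted in the test suite rather than assumed.

Rasters are block-aggregated to 2 × 2 km analysis units — sums for
extensive layers (areas, ESV, allocated totals), means for intensive ones
(NDVI, light). Partial edge blocks keep their partial sums: renormalising
them would silently inflate boundary units and break conservation, and
irregular study-area boundaries make such units unavoidable in practice.
Land-use areas become percentages of the unit area (0–100), and every
factor column plus the response is z-standardized with population-SD
normalization, the parameters stored for later back-transformation.

One genuinely open choice: land-use percentages can either be z-scored like
all other inputs (the default) or passed through on the 0–100 scale
(`standardize_landuse = FALSE`). Either way, response-curve sweeps for
land-use factors are configured on the interpretable percent scale and
converted to the model's input scale internally.

## The surrogate and its training conditions

The network is dense 128 (linear) → dropout 0.3 → dense 256 (tanh) →
dropout 0.3 → dense 16 (ReLU) → dropout 0.3 → dense 1 (linear). The first
dense layer is kept genuinely linear rather than silently upgraded to a
nonlinearity; the 16-unit ReLU layer is the penultimate feature layer. The
implementation is plain R matrix code authored in this package — forward
pass, backpropagation, inverted dropout, seeded Glorot-uniform
initialization and ADAM — because the surrogate and its disassembly are the
package's core, and every detail (especially determinism) must be
controlled.

Training uses MSE loss, a 70/30 train/test split by seeded shuffle, and 200
epochs. Hyperparameters not pinned down by the architecture are fixed at
the framework defaults of the era: learning rate 1e-3, β₁ = 0.9,
β₂ = 0.999, ε = 1e-8, batch size 32, no early stopping; all are recorded in
the config object. Dropout is active only during training, so inference is
deterministic — the response analysis presumes a deterministic function.
Every random draw (initialization, split, batch order, dropout masks) comes
from the single config seed, making training bit-reproducible.

Fit quality is reported as Nash–Sutcliffe efficiency and RSR. Both use
population (n) normalization so that NSE = 1 − RSR² holds exactly on the
same sample; the conventional "satisfactory" grade applies when NSE > 0.5
and RSR ≤ 0.70. Reported metrics are test-set values.

## Response analysis: parameters and conventions

* **Sampling domain** — default is the observed standardized range of the
  factor (percent scale 0–100 for land-use columns); wider printed domains
  can be supplied per factor, since extrapolation beyond the data range is
  a user decision, not a default.
* **Sweep resolution** — 201 points per curve, 51 × 51 for pair surfaces.
  Grid-refinement tests confirm ranges and feature contributions move by
  less than 2 % of the curve amplitude when density increases tenfold, so
  finer grids buy nothing.
* **Intensity thresholds** — ES at range ≥ 0.2, S at ≥ 0.1, NS below, on
  the standardized ESV scale. Thresholds are inclusive upward: the
  boundary value 0.2 grades ES. With that convention intensity is a
  monotone function of range (asserted as a property test).
* **Shape taxonomy** — curves are smoothed with a 5-point centred moving
  average, then collapsed into significant monotone segments by a
  reversal-excursion (zigzag) filter: a direction counts only once the
  curve moves 2 % of its amplitude (`flat_tol`) in that direction, and
  reverses only after an opposing excursion of the same size. Zero
  direction changes give a monotone label, one change a U or inverted-U,
  more than one a fluctuating label signed by the net change. The
  excursion formulation (rather than thresholding individual first
  differences) makes the flat tolerance independent of sweep density: a
  per-step threshold of 2 % of amplitude would flag *every* step of a
  smooth 201-point curve as flat, since adjacent steps move about
  amplitude/200. An entirely flat curve returns a monotone label carrying
  a `zero_range` attribute instead of failing.
* **Extrema** — for U / inverted-U curves the smoothed curve's extremum is
  reported, back-transformed to original factor and ESV units via the
  stored standardization parameters; monotone curves return the attaining
  endpoint with a `monotone` flag. The reported point is the curve's
  extremum, not a second-derivative zero.

## Synergistic features and the PCA contrast

A feature's *weight* is the magnitude of its output-layer coefficient
`|w_j|`; its *contribution* from factor *i* is `|w_j|` times the range of
activation `h_j` under factor *i*'s single-factor sweep — the weighted
range of the response routed through that neuron. Factors whose
contribution reaches `theta_contrib` (default 3e-4 on the standardized ESV
scale) form the feature's contained set; features with non-empty contained
sets are retained, ranked by weight (the weight threshold defaults to 0).
These operationalizations are declared conventions: they are the simplest
constructions consistent with the exact linear decomposition of the output
layer. The PCA baseline (`stats::prcomp` on the standardized factor
matrix) reads each component's contained factors as those with loading
magnitude ≥ 0.1. Feature labels ("city-scale factor" and the like) are
human annotations; the package stores a free-text slot and never
auto-names. Features are not claimed to be identifiable across
retrainings.

## What the synthetic generator emulates — and what it does not

`generate_landscape()` produces the data model the fusion stage expects,
with the statistical structure the analysis assumes: spatial
autocorrelation (white noise smoothed by a Gaussian kernel of width
`spatial_corr_length`, default 6 km), land-use fractions that close to the
cell area via a softmax over smoothed fields, population / GDP / light
surfaces co-varying with construction land, and a ground-truth ESV equal to
the per-class coefficient expansion plus Gaussian noise (default SD 10 % of
the signal SD). The default 64 × 64 km grid at 1 km yields 1024 analysis
units after 2 km aggregation — the same order as a mid-sized city's grid
sample, and large enough to train the surrogate while keeping a full
pipeline run under a minute. Default coefficients rank water > woodland >
grassland > cultivated > unused > construction; magnitudes are arbitrary
stand-ins, configurable, and never calibrated to any published valuation
table. City totals default to round numbers of plausible magnitude for a
large city; only their allocation pattern, not their absolute scale,
matters after standardization.

What passing tests on this landscape therefore show: the pipeline's
accounting (conservation, closure, standardization), the surrogate's
ability to learn a smooth land-use-driven ESV, and end-to-end determinism.
What they do not show: performance under real-world measurement error,
land-use misclassification, non-Gaussian spatial structure, or a genuinely
weak factor–ESV signal — on real data NSE near 0.5, not 0.99, is the
realistic regime.

`generate_oracle_table()` drops the spatial layer entirely: equicorrelated
standard-normal factors and a response that is a sum of planted closed-form
effects (linear slopes, signed quadratics with stated vertices) plus noise,
with the truth record returned alongside. Recovery tests run at n = 2000
with planted amplitudes at least three times the noise SD across ten seeds,
requiring the top-two planted factors to top the response ranges and their
shapes and vertices to be recovered in at least eight of ten — a deliberate
margin, since one seed can always land an unlucky initialization.

## Numerical choices and degenerate inputs

Zero-variance factor columns abort standardization with an explicit error:
a constant factor cannot be swept and silently dropping it would desync the
23-column contract. All-zero weighting layers refuse allocation. Training
reports divergence (non-finite loss) by epoch rather than returning NaNs.
Aggregation with block 1 is the identity; degenerate (zero-width) sweep
domains are rejected. Rasters are exchanged as ESRI ASCII grids — a
plain-text, GDAL-readable format — written at full double precision so
write/read round trips are exact; sample tables travel as CSV with a JSON
sidecar of standardization parameters, and trained surrogates as JSON
weights plus CSV history. The pipeline manifest hashes every artifact, and
a single global seed fans out to per-stage seeds (hashed from the stage
name) so any stage can be re-run alone and reproduce the full-pipeline
result.

## Known limitations

The surrogate is a single MLP, not an ensemble: response curves inherit its
extrapolation wiggles near the sampling-domain edges where data are sparse
(the smoothing window and excursion filter suppress, but cannot eliminate,
spurious shape calls there). Feature extraction quantifies factor content
per neuron but does not test feature stability across retrainings.
Allocation follows a single ancillary layer per indicator; no multi-layer
dasymetric refinement is attempted. No CRS handling or reprojection is
performed — all layers are assumed to share one grid.
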