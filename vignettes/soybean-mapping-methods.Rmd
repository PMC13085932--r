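---
title: "Methods: phenology-driven soybean mapping with soymapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenology-driven soybean mapping with soymapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soymapr)
```

## The problem and the model

Soybean (a dicot) and corn (a monocot) overlap in planting calendar and in
spectral response through most of their growing season. They diverge during
soybean pod-filling: soybean loses canopy water early, so shortwave-infrared
(SWIR) reflectance rises markedly while red-edge reflectance begins a sharp
decline; corn holds peak leaf area through silking and milk stages with
consistently high near-infrared (NIR) reflectance and stable, low SWIR. In
the US corn belt this divergence sits around DOY 220–260.

soymapr operationalizes the mapping recipe built on that window:

1. composite a dated reflectance stack into 10-day medians and fill
   temporal gaps linearly;
2. score candidate features per composite period by the Jeffries–Matusita
   (J–M) separability between soybean and corn samples;
3. pick the contiguous window of periods maximizing mean J–M, and within
   it construct a composite index from the most separable, least redundant
   base features — the second red-edge band (RE2, B6), the first SWIR band
   (SWIR1, B11), and EVI, combined multiplicatively into the soybean
   identification index (NSII);
4. threshold the window-mean index automatically on 70% of the labeled
   samples and validate on the held-out 30%.

## Separability statistics

For classes $j,k$ with Gaussian feature statistics $(\mu_j, \Sigma_j)$,
$(\mu_k, \Sigma_k)$ (sample means; unbiased covariance, $n-1$ denominator):

$$B = \tfrac18 (\mu_j-\mu_k)^\top
      \left[\tfrac{\Sigma_j+\Sigma_k}{2}\right]^{-1} (\mu_j-\mu_k)
    + \tfrac12 \ln
      \frac{\left|\tfrac{\Sigma_j+\Sigma_k}{2}\right|}
           {\sqrt{|\Sigma_j|\,|\Sigma_k|}},
\qquad JM = 2\,(1 - e^{-B}) \in [0,2].$$

The general density-overlap form of the J–M distance is implemented only
through this Gaussian reduction, which is how it is used in practice for
crop separability. The square root over $|\Sigma_j||\Sigma_k|$ is required
for $B=0$ iff the distributions coincide; renderings that drop it break
that identity and are treated as typographical.

Numerical choices:

* a ridge $\varepsilon = 10^{-10}$ is added to the diagonal of **each**
  class covariance before pooling and inversion. Adding it to each class
  (not only the pooled matrix) makes the degenerate limits continuous:
  two identical constant classes give $JM = 0$, constant-but-different
  classes saturate to 2. A pooled-only ridge would produce
  $\ln(\varepsilon/0) = \infty$ for identical constant classes.
* log-determinants are computed via `determinant()` rather than products
  of eigenvalues, for scale stability.
* the per-feature separability matrix is univariate J–M per
  feature × period (matching the heatmap practice in this literature);
  multivariate J–M over feature sets is available through the same
  `class_stats()`/`jm_distance()` pair but is not used for window
  selection. Cells with fewer than two finite values in either class are
  masked and counted, never fatal.

Window selection is an exhaustive scan over all contiguous period runs
within the length bounds, maximizing the arithmetic mean of the
within-window cells ("average separability" is not otherwise specified in
this literature; the mean is the obvious aggregator). Ties prefer the
earliest start, then the shortest window. The scan is trivially cheap at
seasonal scale (≤ ~20 periods) and is itself the reference its tests
compare against.

## The index formulary and NSII

`index_registry()` carries the full 35-index formulary plus GCVI and NSII
as arithmetic expression strings over band symbols; `compute_feature()`
evaluates them per pixel with sub-feature resolution (SMCI references EVI
and GCVI; GWCCI references NDVI's band expression). Two conventions:

* **Mask, don't throw.** Any non-finite result (zero denominators in
  ratio indices, negative square-root arguments) masks the pixel. Index
  maps inherit the union of their input bands' masks.
* **Fidelity tags.** Several circulating printed forms of classic indices
  are degenerate (an `MSRre` that is identically 1, an `RDVI` identical to
  NDVI, a `WDRVI` with a malformed denominator, an `MSAVI` missing its
  square root, an ambiguous `TVI`/`WRI` bracketing). The registry stores
  the canonical published form for these, tagged `canonical_corrected`;
  well-defined printed forms are tagged `as_printed` (including `SR`,
  which duplicates `RVI` as printed). The tag is part of the public
  record so downstream users can see exactly which formula produced a map.

NSII is the composite of RE2, SWIR1 and EVI. The printed form
"RE2×SWIR1×EVI3" is ambiguous between a cube root over the triple product
and an EVI-cubed factor. The default is the cube root,
$\mathrm{NSII} = \sqrt[3]{\,\mathrm{RE2}\cdot\mathrm{SWIR1}\cdot\mathrm{EVI}\,}$,
because (a) it keeps the index on a reflectance-like scale, and (b) it is
a strictly monotone transform of the raw triple product, so ≥-threshold
classification is identical at the transformed threshold — the choice is
harmless exactly where the index is used. The literal
$\mathrm{RE2}\cdot\mathrm{SWIR1}\cdot\mathrm{EVI}^3$ rendering is kept
behind `form = "product"`; note it weights EVI differently and is *not*
order-equivalent to the other two. The cube root is sign-preserving:
negative products (water/soil pixels with negative EVI) map far below any
soybean threshold instead of going missing.

The combinatorial search behind the index construction enumerates every
expression using each selected base feature exactly once, combined with
operators from {+, −, ×, ÷} over both ternary parenthesizations and all
operand orders, optionally wrapped in a reciprocal or cube root. The
candidate universe of the original construction is not recorded anywhere;
this grammar is a declared superset of the operations named there
(addition, subtraction, multiplication, division, reciprocal). Duplicates
under algebraic identity (commutativity and friends) are removed by
numeric fingerprinting on fixed positive probe points; candidates singular
on all samples are dropped with a count. Scoring is mean within-window
univariate J–M; the ranking is deterministic (score, then expression
string).

## Compositing conventions

* Periods are anchored at the season start (not calendar decades), tile
  the season without overlap, and the last period truncates at the season
  end. The anchor is configurable by changing the season start.
* Even-count medians take the mean of the two central values.
* Gap filling interpolates linearly against period midpoints (days since
  season start); leading/trailing gaps extend the nearest valid value,
  since linear interpolation is undefined there. A pixel-band with a
  single valid period is filled constant; zero valid periods stays masked
  and is counted.
* `fill_flag` marks exactly the cells whose values came from
  interpolation or extension.

## The automatic threshold

The classifier is the rule $value \ge T$. Starting at the midpoint of
$[T_{\min}, T_{\max}]$, the search computes precision, recall and F1 at
the current $T$, then bisects toward the half-interval indicated by the
precision/recall comparison, accepting a move unless F1 strictly worsens
and returning the best-F1 threshold seen. Three design decisions deserve
explanation:

* **Direction logic.** For a ≥-rule, raising $T$ raises precision and
  lowers recall, so $P > R$ means the threshold is too *high*. The default
  `"consistent"` mode therefore moves $T$ down when $P > R$. The opposite
  pairing ("$P > R$ ⇒ commission too large ⇒ threshold too low ⇒ move
  up") circulates in print; it contradicts the monotonicity of $P$ and
  $R$ in $T$, but is preserved verbatim as `direction_mode = "as_printed"`
  because the F1-acceptance step partially self-corrects it — on linearly
  separable data both modes reach F1 = 1 (a tested property).
* **Ties and overshoots.** On clustered sample values, consecutive
  bisection midpoints often fall in the same inter-class gap (an F1 tie),
  and a midpoint-of-half-range jump can leap past the optimum (a strict
  F1 drop straight from iteration 1). A tie therefore continues in the
  indicated direction; a strict drop shrinks the indicated half-interval
  (halving the step) and gives the opposite half one probe before the
  next directed attempt. Termination is guaranteed by the interval
  tolerance ($10^{-6}$ of the range) and a 60-iteration cap. An exact
  $P = R$ balance probes one F1-improving move in each direction before
  stopping.
* **Boundaries and degeneracy.** Pixels equal to $T$ classify as target
  (≥ rule; boundary handling is otherwise unspecified in this
  literature). Constant values return that value flagged degenerate, with
  metrics computed at the single cut. Zero-denominator metrics (empty
  predicted-positive or actual-positive sets) take the defined value 0
  and a `degenerate` flag, so extreme thresholds never crash the search.

`grid_threshold_oracle()` — exhaustive F1 over 1000 even cuts plus all
midpoints between sorted unique values plus the minimum itself (ties to
the lowest cut) — is shipped as a first-class function, used by the tests
as the independent reference. On instances shaped like the method's
inputs (two shifted unimodal class distributions, separation 0.5–4 sd,
prevalence 0.2–0.8) the bisection lands within 0.05 of the grid optimum
across 100 seeded instances (a tested property). The inherent limitation:
when labels carry no signal at all, sampling noise creates local F1
maxima in distant basins that *no* local search crosses; on such
instances only the analytic all-positive baseline $2p/(1+p)$ is
guaranteed (also tested). Thresholds are fitted per labeled sample set —
one threshold per region — mirroring the fact that optimal thresholds
differ across regions; all 70% threshold-role samples are used at every
iteration.

Sample handling before fitting: greedy distance thinning in a seeded
random visiting order (a point is kept iff ≥ 30 m — three 10 m pixels —
from every kept point) to curb spatial autocorrelation, then a stratified
70/30 split per class. Both stages are deterministic given the seed.

## The synthetic scene generator

`generate_scene()` emulates exactly the features the pipeline consumes:

* a jittered rectangular field mosaic (field edges 8–14 px ~ 80–140 m)
  with classes assigned by largest-remainder rounding of the configured
  proportions (default soybean/corn/other = 0.4/0.4/0.2), so every class
  with nonzero share is present;
* per-class per-band double-logistic reflectance trajectories
  $base + amp\,[\sigma(k_g(t-t_g)) - \sigma(k_s(t-t_s))]$ — the standard
  remote-sensing growth-curve form — with negative amplitudes for bands
  that dip during the green season (visible, SWIR);
* independent Gaussian noise per observation (default sd 0.01
  reflectance), clipping to [0, 1], and per-date per-pixel cloud gaps
  (default probability 0.05);
* stratified sample points drawn from the truth raster under the same
  30 m spacing rule (default 80 per class on the default 80 × 80 grid,
  which comfortably hosts that intensity under the spacing constraint).

The default "U1-like" preset encodes the qualitative divergence anchors
as curve parameters: soybean SWIR senescence at DOY 222 (sharp,
rate 0.18/day) so SWIR1 rises through the window; soybean
chlorophyll/structure senescence at DOY 268 so red-edge and NIR hold,
then drop at the window's end; corn senescing at DOY 272 with a higher
NIR/red-edge amplitude and low stable SWIR until then; an "other" class
(early small grains) senesced by DOY 200. Under these curves soybean
NSII exceeds corn NSII by ~0.05–0.09 throughout DOY 225–255 while the
"other" class sits far below both, which is what makes the designed
window recoverable by the J–M scan and the scene mappable by a single
threshold — both asserted by tests, not assumed. The parameters were set
from this curve algebra once; they are study conditions, not tuning
knobs.

What the generator does **not** emulate — and therefore what passing
tests do not show about real imagery: band-to-band correlated noise
(correlation enters only through the shared class curves), mixed pixels
at field edges, atmospheric and BRDF artifacts, spatially correlated
cloud structure, within-class variety/management variability, and label
noise in the reference data. Real-scene accuracies will be lower than
the clean-scene recoveries tested here; the tests demonstrate
correctness of the machinery, not expected field performance.

## Input/output conventions

Rasters travel as baseline TIFF files with a JSON sidecar
(`<file>.aux.json`) holding georeferencing (top-left origin, square pixel
size, CRS string), page/band names and the value scaling: float payloads
are affinely mapped onto [0, 0.9] and stored at 32-bit depth
(quantization ~2×10⁻¹⁰ of the value range), with 1.0 reserved as the
nodata sentinel; classification maps use exact 8-bit 0/1/255 coding.
Internally nodata is always `NA`; sentinels exist only at file
boundaries. Pixel indices are 1-based with pixel-center registration
(`R/coords.R` is the single home of the convention); 20 m bands are
upsampled to the 10 m grid on read, nearest-neighbour by default because
it preserves the reflectance distribution (hence class statistics and
J–M values), with bilinear available by flag since the resampling kernel
used upstream of such analyses is typically unrecorded. Mismatched CRS
strings are a hard error — the package deliberately ships no
reprojection engine.

## Problem sizes

The shipped tests run the full pipeline on 40 × 40 and 80 × 80 pixel
scenes with a 5-day revisit over DOY 120–300 (37 dates, 10 bands), 100
threshold-search instances of n = 200, and 1000-pixel registry
verification — sizes chosen so the entire suite completes in well under
a minute while still exercising every code path at realistic seasonal
depth. All randomness flows through explicit seeds (`withr::with_seed`),
and the scene generator is bit-reproducible given its seed.

## Known limitations

* The J–M saturation at 2 happens at double precision once
  $B \gtrsim 37$; beyond that, separability differences are not
  representable (the tests assert strict monotonicity below the ceiling).
* The threshold search is local by construction (see above); it inherits
  the printed algorithm's blindness to multi-modal F1 landscapes.
* The expression search is bounded to templates using each base feature
  once; it will not discover weighted or repeated-feature forms.
* No reprojection, no atmospheric correction, no cloud detection: masks
  and harmonized grids are inputs, as they are in the upstream
  processing chains this package models.
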