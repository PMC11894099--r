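---
title: "Quantifying nuclear plasticity in confined immune-cell migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear plasticity in confined immune-cell migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nucleodyn quantifies how the nuclei of migrating immune cells deform as
their tissue environment becomes more confining — from open
extracellular space to narrow vessel-like channels. The package covers
the whole measurement chain: simulating ground-truthed movies,
segmenting nuclei in 4D fluorescence stacks, tracking them through
time, reducing each track to shape and migration statistics, and the
companion fluorescence-intensity and vessel-geometry analyses.

```{r setup}
library(nucleodyn)
```

## The shape factor and the squeezing definition

The central observable is the **shape factor (SF)** of a nucleus's 2D
maximum projection. From the central second-order area moments of the
binary mask (each pixel treated as a unit square, so the region
covariance is the pixel-centre covariance plus 1/12 on the diagonal),
the eigenvalues $\lambda_1 \ge \lambda_2$ of the inertia tensor give
equivalent-ellipse semi-axes $a = 2\sqrt{\lambda_1}$,
$b = 2\sqrt{\lambda_2}$. The default SF is

$$SF = \frac{a - b}{a + b},$$

which is 0 for an isotropic round region and approaches 1 with
elongation. The published description of this measure ("the long and
the short axis from the integral over the area") admits a second
reading, $1 - b/a$; both satisfy the stated limits. We declare
$(a-b)/(a+b)$ as the default and expose `sf_formula = "aspect_ratio"`
as the alternative. Because the two scales differ, the squeezing
threshold is coupled to the formula: a nucleus is **squeezing** when
$SF \ge 0.4$ under the default formula, and `sf_threshold_for()` maps
that same axis ratio ($b/a = 3/7$) onto the alternative scale
($1 - 3/7 \approx 0.571$). The threshold is inclusive: a frame at
exactly 0.4 counts as squeezing.

A **squeezing event** is a maximal run of consecutive squeezing frames;
its duration is the run length times the frame interval. Missing
frames (bridged by gap closing during tracking) break runs rather than
interpolating SF — we never fabricate a deformation measurement. The
**squeezing proportion** of a track is the fraction of observed frames
at or above threshold.

Circularity $C = 4\pi A / P^2$ uses a Crofton 4-direction perimeter
estimate; naive pixel-edge counting inflates the perimeter of a disk by
roughly 11% and would bias $C$ well below 1. Feret diameters come from
rotating calipers over the convex hull of the pixel *corners* (so a
50 × 20 px rectangle has min Feret exactly 20 px); the min Feret is the
automated analogue of a manual "minimum nuclear diameter" measurement.

## The synthetic-movie generator

No primary imaging data accompany the quantification this package
re-implements, so the generator is a first-class module: every
downstream stage is validated against movies whose ground truth is
known by construction.

Squeezing dynamics are generated per nucleus as a two-state Markov
chain (round/squeeze) with per-frame entry and exit probabilities; the
emitted SF is the state's baseline plus truncated Gaussian jitter
(sd 0.03 by default, truncated at 4 sd and at the 0.4 boundary so the
ground-truth squeeze flag is exactly `sf >= 0.4`). The two built-in
regimes encode the qualitative contrast between environments:

| parameter | open | vessel | meaning |
|---|---|---|---|
| `p_enter_squeeze` | 0.05 | 0.15 | per-frame entry probability |
| `p_exit_squeeze` | 0.50 | 0.25 | per-frame exit probability |
| `sf_baseline` | 0.20 | 0.25 | SF in the round state |
| `sf_squeeze` | 0.50 | 0.65 | SF while squeezing |
| `channel_width_um` | — | 6 | vessel confinement |

With a 30 s frame interval (40 frames span the standard 20-min imaging
window) the vessel defaults give a stationary squeezing occupancy of
$p_{enter}/(p_{enter}+p_{exit}) = 0.375$ and mean episodes of
4 frames = 2 min, versus ~0.09 occupancy and 1-min episodes in the
open regime — more frequent and longer deformations under confinement,
which is the direction of the published contrast. The nuclear diameter
(5 µm) sits in the reported 2–8 µm range, the default pixel size of
0.3 µm/px makes the 17-px heatmap bin ≈ 5 µm, and neither the
acquisition interval nor the pixel size is stated in the source
protocol, so both are exposed in the configuration.

Rendering draws each nucleus as a uniform-intensity ellipsoid whose
in-plane semi-axes realise the frame's true SF while conserving
projected area ($a b$ constant), with the major axis aligned to the
instantaneous velocity, Poisson shot noise and Gaussian read noise
applied last. Nuclei are laid out in separate lanes (one channel per
nucleus in the vessel regime) so pairwise centroid spacing stays above
twice the diameter — the regime under which the tracking contract
(purity 1) is defined. Per-nucleus random streams are derived from the
master seed by a stable hash of the nucleus id, so adding a nucleus
never perturbs the others' trajectories.

What the generator deliberately does **not** emulate: point-spread
blur, drift, bleaching, spectral crosstalk, touching or colliding
nuclei, and irregular (non-ellipsoidal) nuclear shapes. Passing tests
therefore demonstrate correctness of the measurement chain on
well-posed inputs, not robustness to densely packed or poorly resolved
real data — segmentation here has no watershed splitting, and the
greedy tracker is validated only at spacings where identities are
unambiguous.

## Segmentation and tracking

Segmentation mirrors the trainable-classifier design: a small
deterministic filter bank per z-slice (raw intensity; Gaussian
smoothing at σ ∈ {1, 2, 4} px; gradient magnitude at σ = 2; Laplacian
of Gaussian at σ ∈ {2, 4}) feeds a ridge-regularised logistic model
(`glmnet`, λ = 0.01) that maps features to a foreground probability
per voxel. The probability map is thresholded inclusively at 0.5,
26-connected 3D components are labelled (Rcpp union-find), components
below 30 voxels are removed, and labels are renumbered by descending
volume. The interactive feature set, probability threshold and minimum
object size of the original interactive pipeline are unreported, so
all are configuration parameters; the defaults above are declared, not
inferred. Convolutions use replicate boundaries, implemented as cached
banded-matrix products for speed.

Tracking is greedy nearest-neighbour linking with gap closing:
candidate (track, detection) pairs within `max_disp_um` (scaled by gap
length, default 10 µm per 30-s step with `max_gap = 1`) are matched in
order of ascending distance with deterministic tie-breaks (lower track
id, then lower label), making the result independent of detection
order. This diverges from global LAP assignment deliberately: at the
nucleus densities of interest the two coincide, and the greedy rule is
exactly reproducible. Tracks with fewer than 4 timepoints are excluded,
and with a vessel mask supplied, tracks whose majority of centroids
fall outside it are excluded — the majority rule is our
operationalisation of "outside vessels", which the source protocol does
not define for partial overlap.

## Track summaries, correlations, heatmaps

Track length and Euclidean distance are standardised to 15 min: longer
tracks are truncated at the first contiguous 15-min window, shorter
ones are linearly rescaled by $15/T$ and flagged (`rescaled`), since
"standardised to 15 min" does not specify the short-track rule.
**Persistence** is the Euclidean-to-path-length ratio over that window
(the directness reading — it is listed alongside track length and
Euclidean distance, which suggests a ratio rather than a directional
autocorrelation); it is undefined, and excluded rather than set to
zero, for a stationary track. Mean speed is the mean instantaneous
frame-to-frame speed ("average migration speed" is ambiguous; the
instantaneous mean is stated as our choice).

Correlation matrices default to Spearman (rank transform with average
ranks, then product-moment) with two-sided p-values from the
$t$-approximation on $n-2$ degrees of freedom, pairwise-complete over
records. Spatial SF heatmaps bin centroids on a 17-px (~5 µm) grid
under half-open intervals $[ks, (k+1)s)$ — a centroid exactly on a
boundary belongs to the higher-index bin — and report per-bin mean SF
with empty bins flagged as no-data. The heatmap window length is a
parameter because the published legends use both 20-min and 2-h bases.

## Intensity quantification

Lamina rim intensity reproduces the manual line protocol
deterministically: three evenly rotated diameters through the rim
annulus, averaged over the three central z-slices, minus the mean of
three background lines at the same slices. Corrected values can be
negative; they are retained and flagged, never clamped, because
clamping would bias group means. Hemocyte values are normalised to the
epithelial mean of the same age group. The lamin stoichiometry table
uses **medians** per age and channel, normalises each channel to its
reference-age median, and reports the ratio of normalised medians
(A-type over B-type), which is 1 at the reference age by construction.
3D nuclear damage scores subtract a negative-control mean per batch.
All of these are invariant to uniform intensity offsets, and the
normalised quantities to uniform rescaling.

## Vessel transit

Vessel diameter is the distance between the two outermost intensity
peaks above half the profile's dynamic range along a measurement line,
with 3-point parabolic sub-pixel refinement, averaged over parallel
lines (the manual protocol averaged 4–8 diameters per vessel). The
transit interval is detected from the nuclear channel: frames where the
between-wall intensity exceeds the background mean + 3 sd. Derived
metrics: relative change $D_{during}/D_{pre}$ and residual space
$D_{during} - D_{nucleus}$, with $D_{nucleus}$ taken as the nuclear
min-Feret in the transit frame (the published "nuclear diameter" is not
further specified; min-Feret is our declared choice). The peak
criterion and parabolic refinement are artifact decisions — the
original measurement was manual on in-focus planes.

## Numerical choices and degenerate inputs

- Inclusive thresholds throughout (SF ≥ 0.4, probability ≥ 0.5,
  component volume ≥ minimum), mirroring the inclusive squeezing
  definition.
- Line sampling and sample counts use a 10⁻⁹ epsilon before
  rounding/ceiling so nuclei with identical geometry at different
  absolute positions measure identically despite floating-point noise.
- Classifier weights serialise as 17-significant-digit decimal strings;
  a reloaded classifier reproduces probabilities bit-identically.
- Zero-variance attributes yield NA correlations with a warning, not an
  error; empty masks and missing labels raise typed conditions
  (`nucleodyn_empty_mask`, `nucleodyn_not_found`,
  `nucleodyn_unmeasurable`).
- When every annotated feature is constant the classifier falls back to
  the class-prior log-odds with zero weights and warns that the classes
  are not separable.

## Validation design and problem sizes

The test suite validates each stage against independent oracles
(explicit double-sum moments, run-length-encoding event detection,
exhaustive Feret vertex pairs) and the full chain by parameter
recovery: 20 seeded vessel-regime movies (50 nuclei, 40 frames at
30 s, 3 z-slices, 160 × 200 px fields) are segmented, tracked and
summarised, and the recovered squeezing occupancy, event durations and
tracking purity are compared with the generating Markov parameters.
These sizes keep the recovery statistically meaningful: at 50 × 40
autocorrelated frames the pooled occupancy estimator has a sampling SD
of ~2 percentage points, so occupancy is checked on the proportion
scale (±5 points). Mean event duration is compared with $1/p_{exit}$
within 15%, which absorbs the downward censoring bias (~7% at these
settings) from events truncated by the 40-frame window — the event
detector reports what is observable, exactly as the manual protocol
would.

## Known limitations

- 2D shape only (per the projection-based protocol); no 3D sphericity.
- No splitting of touching nuclei and no motion-model prediction;
  dense fields will merge or swap identities.
- The SF formula is a declared default, not an inference of the
  original authors' intent; results on the alternative scale are not
  numerically comparable without remapping the threshold.
- Intensity tools assume flat illumination; there is no flat-field
  correction or colocalisation analysis.
- The vessel tools measure straight, user- or fixture-defined
  measurement lines; arbitrary curved vessel walls are out of scope.
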