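---
title: "Methods: estimators, defaults, and their limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimators, defaults, and their limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexmosaic)
```

This vignette documents the statistical and numerical choices behind
`cortexmosaic`: what each estimator computes, why the defaults are what
they are, which biases are known and accepted, and where the synthetic
generators stop being realistic.

## Coordinate conventions

All coordinates are micrometers. Image arrays are `[x, y, z]` with y
increasing with cortical depth; pixel centers map to
`origin + (index - 0.5) * pixel_size`. Intensities (cells/mm²) and
areas (mm²) follow the units conventional in the anatomy literature,
so a 1 × 1 mm window has area 10⁶ µm² = 1 mm².

## Point processes used as ground truth

- **CSR** (homogeneous Poisson): `N ~ Poisson(λ|W|)`, locations
  uniform. The calibration reference for every estimator.
- **Matérn type II** hard core: a Poisson proposal at intensity λ_p is
  thinned by random marks — a point survives only if no other proposal
  point with a smaller mark lies within the inhibition radius h. No two
  survivors are closer than h, and the retained intensity has the
  closed form `(1 - exp(-λ_p π h²)) / (π h²)`, which the test suite
  checks.
- **Thomas** cluster process: Poisson parents, each with
  `Poisson(offspring_mean)` children displaced by an isotropic Gaussian
  of sd σ. Parents are simulated in a window dilated by 4σ so clusters
  straddling the edge contribute their in-window children; without the
  dilation the child intensity would sag near the border.

Layered patterns (`sample_layered_pattern`) are piecewise-CSR: within
each annotated layer the pattern is uniform at that layer's intensity.
This reproduces laminar profiles but no within-layer depth gradients.

## Layer geometry

Annotations are ordered x-monotone boundary polylines (one more than
there are layers); L1 is excluded by construction, so the top boundary
is the top of the first analyzed layer. Thickness between two
boundaries follows the measuring-lines procedure: points every 1 µm of
arc length along the lower boundary, the same number of points spread
equally along the upper one, matched pairwise distances, median. For
straight parallel boundaries this is exact; it is invariant under rigid
motions because arc-length resampling commutes with isometries. An
all-pairs variant exists (`all_pairs = TRUE`) for sensitivity analysis
only — it systematically exceeds the perpendicular gap.

Layer membership interpolates each boundary's depth at the point's x; a
point exactly on a boundary belongs to the layer above it (toward the
pia), so layers partition the ROI and layer counts sum exactly to the
total. Areas come from the shoelace formula on the layer polygons.

## Nearest-neighbor distances

`nnd()` applies no edge correction: distances are measured to the
nearest in-window neighbor, the convention the downstream summaries
assume. Near the border the true nearest neighbor may lie outside the
window, so the estimator carries a small upward censoring bias —
about +6% in the mean at 100 cells/mm² in a 1 × 1 mm window, shrinking
with intensity. When validating against closed forms for the unbounded
process (Poisson mean NND `1/(2√λ)`, CV `√((4-π)/π) ≈ 0.5227`), use
`periodic = TRUE`, which wraps distances toroidally and removes border
censoring entirely; it is never the default for real data.

## Pair correlation function

The estimator is

$$\hat g_{AB}(r) = \frac{1}{2\pi r\, \hat\lambda_A \hat\lambda_B\,}
  \sum_{i \in A}\ \sum_{j \in B,\, j \neq i}
  \frac{\kappa_h(r - d_{ij})}{|W \cap W_{x_j - x_i}|}$$

with the Epanechnikov kernel κ_h (half-width h), translation
edge-correction weights `|W| / |W ∩ W_v|`, and `λ̂ = n/|W|` ("the
density of the entire field"). Numerical choices:

- **Bandwidth.** Stoyan's rule `h = 0.15/√λ` on the pooled intensity
  (λ in cells/µm²): ≈ 15 µm at 100 cells/mm². Wider bands smooth away
  short-range structure; narrower ones get noisy below ~10 expected
  pairs per band.
- **Intensity convention.** Within-type estimation uses `λ̂² = (n/|W|)²`
  rather than the small-sample `n(n-1)/|W|²` convention, following the
  plain field-density definition. The resulting `(1 - 1/n)` downward
  bias is ≈ 1% at n = 100 — visible as mean ĝ ≈ 0.988 rather than 1.000
  in the acceptance target, comfortably inside its ±0.05 band.
- **Edge correction.** The translation weight is exact for rectangles.
  For polygonal windows the set covariance `|W ∩ W_v|` is evaluated
  from an FFT autocorrelation of a rasterized window mask (≈ 256 cells
  along the longer side, bilinearly interpolated, cached per window);
  on rectangles expressed as polygons it agrees with the closed form to
  < 2%.
- **r grid.** Defaults to 100 values up to a quarter of the shorter
  window side; values beyond half the extent are trimmed with a warning
  because the translation weight diverges as the overlap vanishes.
- **Stability.** Below 10 points per type the estimate is computed but
  flagged `unstable`.

### Envelopes

`csr_envelope()` simulates the null (CSR with the observed counts, or
independent resimulation / random relabeling for cross-type pairs) and
offers two band constructions. The default pointwise band takes
2.5/97.5 percentiles at each r: correct per distance, but a null curve
will typically cross it somewhere along a fine grid. The `"global"`
band is simultaneous: mean curve ± a common multiple of the per-r
simulation sd, the multiplier set to the 95th percentile of each null
curve's maximum studentized deviation, so ~95% of null curves lie
inside over the whole grid at once. Use the global band for "does the
curve stay consistent with randomness at all r" questions, the
pointwise band for distance-localized effects such as an inhibition
zone.

### Replicate averaging

`average_pcf()` is the unweighted pointwise mean after interpolation to
the first estimate's grid; `aggregate_pcf()` applies it twice (ROIs
within mouse, mice within group), mirroring the scalar two-level rule.

## Segmentation chain

`segment_cells()` is a deterministic composition: median projection →
difference of Gaussians → CLAHE → automatic global threshold →
distance-transform watershed → size/circularity particle selection.

- **Median projection** (default 4 slices ≈ 8 µm at a 2-µm z step)
  yields a thin optical section and suppresses structures present in
  only one or two slices.
- **DoG** with σ₂ = 2σ₁ and σ₁ = 4 µm — slightly below the smallest
  expected soma radius (~5 µm) — passes soma-scale blobs while
  rejecting fine processes and slow background.
- **CLAHE** (tile 128 px, clip 3 by default) normalizes staining and
  illumination variability so one global threshold is meaningful. On
  low-dynamic-range synthetic scenes a strong clip amplifies cell-free
  background tiles and can destabilize the threshold; the validation
  scenes therefore run clip 1.5 (see below).
- **Threshold**: iterative intermeans (ISODATA), the behavior behind
  common tools' default automatic threshold; Otsu is pluggable.
- **Circularity** is `4πA/P²` with the perimeter from 8-connected
  boundary tracing plus π pixels: the traced polygon passes through
  boundary pixel centers, half a pixel inside the true outline, and
  dilating a convex outline by half a pixel adds exactly 2π · ½ to its
  length. Without this term small digital disks score up to ~1.09 and
  are wrongly rejected by any cutoff near 1. The default upper bound
  1.05 tolerates the residual digitization error.
- **Defaults vs. scene-matched settings.** The package defaults
  (area ∈ [40, 400] µm², circularity ∈ [0.5, 1.05]) are generic
  soma-sized bounds. The synthetic validation scenes use settings
  matched to their known geometry — area ∈ [100, 700] µm² because DoG
  plus blur inflates the 113-µm² ideal disk of a 6-µm soma (observed
  blob areas 108–317 µm² across seeds), and a circularity floor of 0.6
  because rendered somata are ideal disks (observed ≥ 0.84) while
  clutter clumps that pass the area gate are elongated (observed
  ≤ 0.59). These are data-dependent tunables, exposed in the
  configuration, chosen on tuning seeds disjoint from the test seeds.

`match_to_truth()` scores detections by greedy one-to-one matching on
sorted distances — not assignment-optimal in general, but equivalent
for well-separated somata, which is the regime the guarantees are
stated for.

## Synthetic renderer: what it does and does not model

Somata are uniform-depth spheres: each optical slice shows the
spherical cross-section at its depth, slices are blurred by a Gaussian
point-spread stand-in, clutter is added as 1-px-wide bright segments
(5–20 µm) spanning two adjacent slices at 60% of soma intensity
(fine processes stain dimmer and are thinner than the optical slab),
then Gaussian noise, clamped at zero. Deliberately not modeled:
anisotropic PSF and depth-dependent attenuation, intensity variation
across cells, non-spherical somata, touching somata, chromatic
aberration between channels, and autofluorescence texture. Validation
scenes use 4-slice stacks so the projection slab spans the full stack —
with a deep stack, somata outside the slab are invisible by design,
which would test the projection rather than the detector.

## Study pipeline

Blinding replaces file names with random `IMG#######` digit codes
(collision-free, seed-deterministic, losslessly reversible).
`run_roi()` computes per-ROI statistics and records per-statistic
failures (e.g. too few cells of a type) instead of aborting the ROI.
`aggregate_study()` averages ROIs within mouse, then mice within group,
both unweighted, with available-case handling and contributing-ROI
counts; the per-mouse table is the intended unit for external
hypothesis tests. Group hypothesis testing itself is out of scope.

## Problem sizes

The validation workload is sized for a desk machine: 1 × 1 mm windows
at 50–400 cells/mm² (n ≈ 50–400, O(n²) distance work in milliseconds),
0.25 mm² rendered scenes at 1 µm/px with 50 somata and 200 clutter
segments, 99-simulation envelopes, and studies of 2 groups × 3 mice ×
3 ROIs. Everything in `analysis/` and the test suite runs in well under
five minutes total on one CPU.
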