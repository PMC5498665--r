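---
title: "Quantifying neuronal differentiation: methods and design notes"
author: "neurimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuronal differentiation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurimetry)
```

# Scope

`neurimetry` implements the quantification stack used to score neuronal
differentiation of cultured cells (the SH-SY5Y neuroblastoma model is the
motivating system): neurite enhancement and length morphometry,
Western-blot densitometry, suprathreshold immunofluorescence quantification,
assay normalization, and the hierarchical weighted statistics that pool
measurements across pictures, replicates and independent experiments. Every
stage can be exercised end-to-end on seeded synthetic images and tables that
carry exact, machine-readable ground truth.

# Neurite morphometry

## Enhancement chain

`enhanceNeurites()` applies, in fixed order: a Gaussian smooth (noise
removal), a Laplacian high-pass (thin bright structures respond strongly), a
median filter (despeckling of the response), and binarization of the
absolute response. Kernel parameters are not dictated by the procedure the
pipeline reproduces, so the defaults are the smallest standard choices
consistent with each role:

* `gaussian_sigma_px = 1` — just enough support to suppress single-pixel
  noise without widening 2–3 px neurites,
* 4-connected Laplacian stencil (the 8-connected variant is available),
* 3×3 median window,
* Otsu binarization of the normalized absolute response.

Otsu's threshold is computed by exhaustive maximization of the between-class
variance over the observed integer histogram, reporting the midpoint of the
gap between the two classes. A constant image yields an all-false edge map;
in explicit threshold selection (`selectThreshold()`) a constant image is an
error, because no two classes exist to separate.

## Length measurement

Neurite length is geometric: the chained Euclidean distance along vertex
coordinates (`polylineLengthPx()`), never a pixel count. For branched
neurites the longest root-to-leaf path is always chosen
(`longestPathLengthPx()`). Pixel lengths convert to micrometres through the
scale-bar calibration `um_per_px` (`calibrateLength()`, `scaleFromBar()`).

Annotation mode — operator-supplied polylines, as in the manual reference
procedure — is the exact path: measuring a generator's own truth polylines
reproduces the stored lengths to numerical precision, and the full
annotation chain (length → calibration → picture mean → count-weighted →
inverse-variance pooling) reproduces the ground-truth pooled mean to
1e-9 relative.

## Automated tracing

`traceNeurites()` is a convenience extension that replaces the operator:

1. Guo–Hall two-subiteration thinning of the edge map. (Zhang–Suen parallel
   deletion was rejected: it erases even-width diagonal bands completely.)
2. Removal of skeleton pixels within a margin of each soma (the soma's own
   edge ring is not a neurite), with soma centres and equivalent radii taken
   from the soma mask.
3. 8-connected component labelling, re-joining clusters nicked apart by
   thinning (gap ≤ 4 px; distinct neurites are farther apart than that).
4. Per component: a geodesic shortest-path tree rooted at the pixel nearest
   the attached soma; kept nodes are the root, forks and leaves.
5. Chain measurement: each kept node's depth is the length of its full
   root-to-node pixel chain after boxcar smoothing (window 5, endpoints
   fixed), corner reconstruction, and Douglas–Peucker simplification
   (2.5 px). Edge weights are depth differences, so root-to-leaf sums equal
   whole-chain measurements. Corner reconstruction addresses a systematic
   artifact: where branch bands merge, the skeleton detours onto the wedge
   bisector; high-curvature apexes are excised and rebuilt as the
   intersection of the flanking straight directions, accepted only when the
   rebuild shortens the window.
6. End correction: thinning erodes the rounded end cap of the band, so each
   leaf is extended along the band (geodesic, forward cone) to the farthest
   reachable band pixel minus the cap protrusion. The protrusion model uses
   the sub-pixel transverse half-width `a` of the half-maximum stroke mask
   of the Gaussian-smoothed image, corrected for the inward curvature-flow
   displacement of blurred level sets, `a − 1/(2a)`.
7. The small gap between the soma boundary and the first retained skeleton
   pixel is restored as a radial root segment; trees shorter than
   `min_length_px` (default 10 px — skeleton stubs, not neurites) are
   discarded, mirroring the implicit operator exclusion of non-neurite
   marks.

**Accuracy.** On synthetic benchmark scenes (five cells, two neurites of
30–55 px, 30% Y-branch probability, noise-free), automated tracing recovers
per-neurite longest-path lengths with a mean absolute error of ≈1.5% and
98% of neurites within 5%. The remaining tail (up to ≈6.5%) is sub-pixel
endpoint and fork noise: at the shortest neurites (30 px) the 5% band is
1.5 px, which is at the quantization floor of skeleton tracing on
anti-aliased strokes 2.5 px wide. Annotation mode has no such floor and
remains the reference path.

# Densitometry

`integratedDensity()` implements the standard gel reading: the sum of pixel
intensities over the user-defined band ROI minus the mean background pixel
intensity (from an equal-sized, non-overlapping ROI near the band) times the
band-ROI area. Subtracting the *per-pixel* mean scaled by area — rather than
a raw scalar from the summed intensity — keeps the quantity dimensionally
consistent. Consequences that tests assert exactly: IDV is invariant to
adding a constant to every pixel and linear in a multiplicative gain.

Digitized X-ray films carry signal as dark bands on light background;
intensities are inverted (`max − pixel`) before summation by default
(`invert = FALSE` for signal-bright data). A negative IDV is legal (noise
can push a faint band below its background); a non-positive loading-control
IDV makes a lane unusable. `enforceUniformRoi()` enforces the rule that one
ROI dimension serves all bands in all experiments. Normalization is
two-stage: first to the lane's loading control (β-actin), then fold change
against the reference condition (`foldChange()`), which maps the reference
to exactly 1 and absorbs per-experiment scale variability.

The default background placement — directly above the band at one
ROI-height offset — is a choice; "an area near the ROI" is otherwise
unconstrained, and the helper validates disjointness.

# Immunofluorescence (RFI)

`suprathresholdSum()` is the cumulative sum of the values of pixels
*strictly above* the threshold — a literal reading of the procedure: raw
values of qualifying pixels, not their excess over the cut.
`rfi()` thresholds and sums the marker and nucleus channels independently by
the same procedure and divides marker by nucleus, correcting for cell
abundance; a zero nucleus sum leaves no normalizer and errors. The default
policy is a pre-determined fixed threshold per channel; Otsu is the fallback
when no value is supplied. Cross-condition comparability assumes identical
acquisition settings; the package can only take that as a declaration.

# Aggregation statistics

The hierarchical chain (`hierarchicalNeuriteMean()`) follows the design of
the sampling: per-picture summaries; picture means within a replicate pooled
with weights equal to the number of measurements taken; replicate means
within an experiment, and then experiment means, pooled by inverse variance
(`w_i ∝ 1/v_i`, pooled variance `1/Σ(1/v_i)`).

Two quantities the procedure's verbal description leaves open are fixed as
follows:

* the variance carried upward from a count-weighted pool is the
  count-weighted sample variance of the member means about the pooled mean
  with the frequency-weights correction `k/(k−1)`;
* a member with zero variance (single value, or identical values) receives
  the smallest positive member variance; if no member has positive
  variance, the pool falls back to count weighting. This keeps the
  estimator defined on small real inputs while preserving inverse-variance
  weighting whenever variances exist.

The pooled `variance_of_mean` tracks *within-experiment* scatter only — it
is the standard error of the inverse-variance combination, not of the
estimator's recovery of a population mean, because between-experiment
variance enters the weights' inputs but not the pooled variance formula. The
package therefore labels `sqrt(variance_of_mean)` explicitly as the pooled
SE, and validation of mean recovery on simulated hierarchies uses the
Monte-Carlo standard error (between-experiment spread over √n), which is
≈3.5× larger under the default variance components.

`oneWayAnova()` is the classical fixed-effects decomposition at 95%
confidence (computed through `stats::oneway.test` with equal variances);
`tukeyHsd()` performs all pairwise comparisons with the studentized-range
statistic in Tukey–Kramer form (exact for the balanced duplicate design,
conservative otherwise) against `qtukey` critical values; the family is
controlled per response variable, with no cross-variable correction.
`determinationCoefficient()` is the R² of the least-squares line, used to
relate indirect cell counts from nuclear staining to metabolic viability
readouts. `normalizeAssay()` divides by protein content when available and
then by the respective control.

# Synthetic data: what it emulates, and what it does not

All generators are pure functions of (spec, seed); identical calls are
bit-identical, and every stored truth equals an independent brute-force
computation on the noise-free scene (segment sums, pixel sums, analytic band
integrals).

* **Neuron scenes** — bright anti-aliased soma disks with piecewise-linear
  neurites (width 2.5 px) of known vertex geometry; lengths uniform on the
  spec range (the length distribution within a picture is not prescribed by
  the reference procedure; uniform is a neutral default). A Y-branch
  replaces the distal part with two arms; truth records the longest
  cumulative path. Cells are placed with non-overlapping neurite
  territories, and neurites of one cell are resampled until their
  centrelines keep ≥ (width + 7) px clearance, so the "non-overlapping
  neurites" study condition holds by construction. Additive Gaussian noise
  is clipped to the 16-bit range.
* **Blots** — isotropic Gaussian bands (σ = 12 px by default, the scale of
  600-dpi film digitization) in film polarity over a linear background ramp
  that runs along columns, so the default background ROI (directly above a
  band, same columns) cancels the ramp exactly. Relative IDV noise scales
  as ≈0.036/σ at noise 2% of band amplitude, which motivates the wide
  default band.
* **Fluorescence pairs** — nucleus disks plus a marker channel positive on
  a chosen fraction of the same objects; truth records the exact
  suprathreshold sums of the quantized noise-free channels.
* **Hierarchies** — Gaussian variance components between experiments,
  between pictures and within pictures around a grand mean, with 15–30
  measurements per picture; replicates differ only through their pictures'
  draws (no replicate-level component).
* **Assay tables** — rows (condition, raw value, protein content) whose
  expected protein-normalized value is the planted fold change times the
  control's, with multiplicative Gaussian noise.

Not emulated (by design): optics (PSF), uneven illumination, film
saturation, cell texture, touching cells, debris. Passing tests on these
scenes therefore validate the *computational* chain — formulas,
normalizations, pooling, thresholding, geometry — not robustness to the
full pathology of real micrographs; the automated tracer in particular is
validated under clean-background, non-overlapping conditions.

# Problem sizes and runtime choices

Validation runs use sizes that keep the full suite fast while leaving no
statistical ambiguity: 384×384 px scenes with 10 neurites each (20 scenes
for tracing validation), 6-lane blots, 192×192 px fluorescence pairs,
1000-replicate null simulations for the type-I error of the ANOVA at
α = 0.05, and 200 simulated experiments for hierarchical mean recovery
within three Monte-Carlo standard errors.

# Known limitations

* Automated tracing carries a ≈1.5 px absolute endpoint uncertainty; on
  neurites shorter than ≈35 px individual measurements can exceed 5%
  relative error (≈2% of neurites on the benchmark scenes). Use annotation
  mode when exactness matters.
* The inverse-variance chain is the reference procedure, not the optimal
  analysis; a mixed-effects model would use the data more efficiently and
  is deliberately out of scope.
* RFI assumes comparable acquisition settings across conditions; the
  package cannot verify this from pixels.
* Densitometry assumes bands are resolved and ROIs user-supplied; no
  automatic band detection, lane straightening or saturation correction.
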