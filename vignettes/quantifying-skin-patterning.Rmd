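---
title: "Quantifying feather primordia patterning and dermal cell anisotropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying feather primordia patterning and dermal cell anisotropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumetrics)
```

## The measurement problem

During avian skin development, dermal and epidermal cells condense locally
into feather primordia — bright spots in DAPI/phalloidin-stained skin that
together form either longitudinal rows (chicken, quail, zebra finch) or
two-dimensional arrays (emu, ostrich, penguins). Two quantitative readouts
characterize this process:

* **Pattern fidelity**: how regular the spacing between neighbouring
  primordia is, summarized as the standard deviation of neighbour
  distances divided by their mean (a dimensionless coefficient of
  variation; lower = more regular).
* **Cell-shape anisotropy**: how elongated, and along which axis, the
  dermal cell texture is, measured without segmenting individual cells.

`plumetrics` implements these readouts together with the time-lapse
machinery needed to follow them in living explants: drift registration,
anisotropy-based automatic region detection, particle image velocimetry
(PIV), velocity-field divergence, and antero-posterior (AP) primordia
tracking with fusion detection. A synthetic-image module generates all the
fixtures the test suite needs, each with planted ground truth, so the
whole pipeline is verifiable without microscopy data.

## Coarse-grained anisotropy by Fourier transform

The frame is tiled with square interrogation boxes (default 25 × 25 µm
with 50% overlap, matching common practice for dermal texture). For each
box:

1. subtract the box mean (an unremoved DC spike would dominate the
   brightest-pixel set and bias the readout toward isotropy);
2. multiply by a 2D Hann window — apodization that avoids the spectral
   cross artifact produced by box boundaries;
3. take the 2D FFT modulus, zero frequency centered;
4. binarize the spectrum by keeping the 5% brightest pixels
   (nearest-rank 95th percentile, ties kept — bit-reproducible);
5. form the second-moment (inertia) matrix of the retained pixel
   coordinates about the origin, with uniform weights, and diagonalize it.

With eigenvalues $\lambda_1 \ge \lambda_2$, the retained set approximates
a filled ellipse with axes $L_{maj}/L_{min} = \sqrt{\lambda_1/\lambda_2}$,
and the **anisotropy amplitude** is

$$a = \tfrac{1}{2}\,\ln\frac{L_{maj}}{L_{min}}
    = \tfrac{1}{4}\,\ln\frac{\lambda_1}{\lambda_2},$$

zero for isotropic texture. Real-space elongation is perpendicular to the
spectral elongation, so the reported **nematic angle** (in $[0, \pi)$,
measured from the AP/row axis) is the orientation of the eigenvector of
$\lambda_2$. Degenerate boxes (constant intensity, or a collinear retained
set) carry amplitude 0 and an `NA` angle, and are excluded from averages.

Averaging over boxes follows the bar representation: the mean amplitude is
the arithmetic mean of bar lengths, while the mean direction is the
orientation of the summed nematic tensor
$\sum_i a_i(\cos 2\theta_i, \sin 2\theta_i)$ — orientations 90° apart
cancel, and a vanishing tensor norm (below $10^{-9}$ of the amplitude sum)
is reported as an undefined direction.

### Validity regime and the closed-form oracle

The synthetic texture is white Gaussian noise convolved with an
anisotropic Gaussian kernel of aspect $\rho$: by the Fourier scaling
theorem its expected amplitude is exactly $\tfrac12 \ln \rho$ at the
planted angle, giving a closed-form oracle for the whole estimator. Two
finite-size effects bound the regime in which one measurement per box is
accurate:

* **Sampling noise.** The amplitude is a folded statistic
  ($\lambda_1 \ge \lambda_2$ by construction), so per-box noise biases it
  upward. The bias shrinks when the retained 5% of spectrum pixels is
  *envelope-dominated* — i.e., the spectrum envelope is comfortably wider
  than the Hann main lobe but narrow enough that thresholding selects a
  compact region. The generator's default texture grain
  (`correlation_length_um = 3` at 1 µm/px) was chosen in this regime: with
  64-px boxes the measured isotropic mean amplitude is ≈ 0.04.
* **Window smearing.** The Hann window convolves the spectrum with its
  own transform; when the spectral minor axis approaches the lobe width
  (coarse grain, large $\rho$, small boxes) the measured aspect is
  compressed toward 1. Stretch-recovery checks therefore use a finer
  1.5 µm grain, where amplitudes for $\rho \in \{1.5, 2, 3\}$ land within
  5% of $\tfrac12\ln\rho$ at 64-px boxes.

Both regimes are exercised by the test suite (isotropy null below 0.05
over ≥ 50 boxes; stretch recovery within 10% and 5° over 20 seeds).

## Primordia detection and pattern statistics

Detection is deliberately simple thresholding, in the spirit of
"Dotfinder"-style detectors: keep the 30% brightest pixels (nearest-rank
quantile), Gaussian-smooth (default σ = 10 px; the original procedure
does not state a value, and σ = 0 disables smoothing for exact-area
analyses), binarize at half the mean of the retained intensities (keeps
blob footprints stable under smoothing), label 8-connected components,
and discard components below `min_area_px` — **inclusive** at the
threshold, i.e., a component of exactly the minimum area is kept. The
default minimum is 10,000 px, overridable in µm² since the cutoff is
scale-dependent. Component centers are intensity-weighted centroids
(weight = intensity above the frame median) so the bright condensation,
not dimmer attached texture, sets the position.

Spacing variability comes in two variants:

* **Row variant** — sample standard deviation (n − 1 denominator
  throughout) of consecutive center-to-center distances along the first
  formed row, divided by their mean.
* **Delaunay variant** — for array-forming patterns, neighbours are pairs
  joined by a Delaunay edge. Edges with a vertex on the convex-hull
  boundary are excluded: border primordia lack outer neighbours, so their
  edges systematically overestimate local spacing. "Boundary" includes
  points lying exactly on hull edges (collinear border points of
  lattices), otherwise a perfect hexagonal test lattice would keep border
  edges that the procedure is meant to drop.

The triangulation is built in-package by sorted incremental insertion
with Lawson flips. No super-triangle is used — near-collinear hull
triangles have enormous circumcircles that a finite super-triangle
corrupts — and pre-sorting points lexicographically makes the handling of
co-circular quadruples a fixed, reproducible function of the input. The
test suite checks exact edge-set equality against a brute-force
empty-circumcircle oracle on 100+ random point sets.

Density is counted in half-open rectangles (a center on a low-coordinate
edge counts, on a high-coordinate edge it does not), normalized per mm².
Explant surface retractation uses the shoelace formula on manually traced
outlines, reported as percent area lost.

## Time-lapse analysis

**Registration.** Translation-only, by integer-pixel phase correlation of
consecutive frames with cumulative shifts removed (borders replicated). A
pair is flagged low-confidence when the correlation peak is below 8
standard deviations of the correlation surface: for unrelated frames the
peak stays near the Gaussian-maximum ceiling $\sqrt{2\ln N} \approx 5$,
while a genuine translation scores orders of magnitude higher.

**Region auto-detection.** From the per-box temporal mean of anisotropy
amplitude, the *competent segment* is the window of 3 adjacent grid
columns with maximal mean amplitude; within it, the inter-primordium
region is the 4 boxes of maximal mean amplitude and the primordium region
the 4 of minimal amplitude. For PIV averaging each region grows to a 3×3
block centered on the 4-box centroid row with its central column forced
to the middle segment column, rows clamped into the grid. Ties go to the
smallest column index and row-major box order, and the two 4-box sets are
kept disjoint (with tied amplitudes the literal max/min sets could
otherwise overlap).

**Smoothing and alignment.** Per-frame series are smoothed with a
centered moving average of nominal width 30 frames (2 h 30 min at 5-min
intervals). A centered symmetric window has odd width, so the interior
window is 31 taps (i ± 15), shrinking symmetrically at the series ends —
this preserves series length and leaves linear trends untouched. Series
are aligned on a reference frame t_ref (the first visible condensation),
which is user-supplied or taken from synthetic ground truth; an optional
heuristic (`estimate_t_ref()`: first frame whose smoothed
primordium-region amplitude falls 2 SD below its leading baseline) is
provided but not used anywhere by default. Multiple aligned movies are
averaged over the intersection of their aligned supports.

**PIV.** Frames are median-filtered (radius 2 px) to suppress impulsive
noise, then each 32-px window (50% overlap) is mean-subtracted,
variance-normalized and cross-correlated by FFT. The correlation surface
is divided by the per-lag overlap fraction — at circular lag $s$ only
$N - |s|$ pixel pairs genuinely overlap, and without this correction wide
correlation peaks are pulled toward zero displacement. The peak is
searched within |lag| ≤ window/4 (the usual PIV validity range), refined
per axis by a 3-point Gaussian fit on the log correlation (parabolic
fallback when a neighbour is non-positive), and validated by a 3×3 median
test: vectors deviating more than 2 px from the neighbourhood median are
replaced by it and flagged. Conversion to physical units multiplies
px/frame by `pixel_size_um × 60 / frame_interval_min` (at 5-min frames,
1 px/frame = 12 × pixel size µm/h).

**Divergence.** $\partial u/\partial x + \partial v/\partial y$ by
central differences on the box grid (one-sided at edges), spacing equal
to the box stride in µm. Negative divergence = contraction/convergence,
the kinematic signature of condensation; the operator is linear and exact
on linear fields, which the tests exploit.

**Tracking.** Per-frame detection followed by nearest-neighbour
association on the AP coordinate only, within a gate defaulting to 1.5 ×
the mean detected blob radius. A detection claimed by two tracks keeps
the nearer track and ends the other, recording a fusion event on the
survivor at that frame — the readout used to evidence primordia fusions.
AP-only matching is a documented limitation for strongly oblique motion.

## The synthetic-data module

The generators emulate just enough structure for every stage to be tested
against planted truth:

* **Texture**: anisotropically filtered Gaussian noise (grain 3 µm,
  intensity 100 ± 30 by default, clipped at 0), with the closed-form
  anisotropy oracle described above. Real dermis has cell walls,
  nuclei and staining gradients that this model does not reproduce; tests
  passing on it validate the estimator's mathematics, not its robustness
  to every imaging artifact.
* **Point patterns**: rows with truncated-normal gaps (truncation at 10%
  of the mean keeps gaps positive while the CV remains the single
  fidelity knob; realized CV is returned as ground truth) and hexagonal
  arrays with isotropic positional jitter calibrated to first order as
  $\sigma = \mathrm{CV}\cdot s/\sqrt 2$ per axis.
* **Blobs**: isotropic Gaussians (sd = radius/2) added to the texture;
  per-blob ground truth records the area above the detection threshold in
  the noise-free image (computed from the blob field against threshold
  minus median texture — exact on flat backgrounds, approximate
  otherwise) and flags sub-threshold blobs.
* **Flows**: kinematic only — uniform drift, whole-field Gaussian
  random-walk steps, and radial sink inflow ($v = -s\,(x - c)$), applied
  as backward bilinear warps with reflective padding, fresh sensor noise
  added after warping. Frame interval defaults to 5 min. These are
  stand-ins for tissue flow; no mechanistic (reaction–diffusion or
  chemotaxis) model of primordia self-organization is included, so tests
  validate measurement, not morphogenesis.

All generators are pure functions of their spec including the seed, and
restore the caller's RNG state.

## Numerical choices and degenerate inputs

* All intensity thresholds use the nearest-rank quantile (sorted value at
  `ceiling(p·n)`), retaining ties — bit-reproducible across platforms.
* Incircle and orientation predicates carry relative tolerances
  ($10^{-12}$ of the term magnitude); co-circular quadruples are resolved
  by the sorted insertion order.
* Constant frames warn and return an empty detection set; constant
  interrogation boxes are degenerate, not errors; flat PIV windows yield
  invalid vectors that are infilled from neighbours but stay flagged.
* Errors carry machine-readable condition classes (`invalid_spec`,
  `frame_too_small`, `no_interior_edges`, `region_out_of_bounds`, ...) so
  callers can branch on failure modes rather than message text.

## Problem sizes in the shipped tests

The suite runs entirely on generated imagery: 192–352 px frames, 64-px
anisotropy boxes, 20-seed averages for calibration checks, 100 random
point sets for the triangulation oracle, 10-seed detection fixtures and
12-frame tracking movies. These sizes were chosen so each property is
measured well inside the estimators' validity regimes while the whole
suite completes in well under a minute on a laptop-class CPU.

## Configuration files

Run configuration (`run_config()`) collects pixel size, frame interval,
box geometry, detector parameters, axis convention and seed; values can
be loaded from a YAML file and overridden per call, and every run writes
its fully resolved configuration alongside the outputs for provenance.

## Known limitations

* The anisotropy amplitude is biased upward on very small boxes or very
  coarse textures (see the validity regime above); compare conditions at
  matched box size and grain.
* PIV assumes locally uniform displacement per window and degrades beyond
  window/4 displacements; choose the window to the expected motion.
* Tracking matches on the AP coordinate only and does not model splits
  (only fusions), mirroring the intended use on AP-directed condensation
  movies.
* The synthetic texture is stationary; it does not emulate bleaching,
  drift in illumination, or cell-scale rearrangements.
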