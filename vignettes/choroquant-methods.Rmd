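---
title: "Methods: volumetric choroidal vascularity from radial SS-OCT scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volumetric choroidal vascularity from radial SS-OCT scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choroquant)
```

## The measurement model

A radial SS-OCT acquisition samples the macula with `n_radials` B-scans
through the fovea at fixed angular steps (default 18 scans at 10°, tiling
the half-circle; each scan contributes two opposite semi-meridians). A
B-scan is a `axial_px x n_alines` intensity image, row 1 on the vitreous
side. The physical frame is fixed by the geometry: laterally
`scan_width_mm / n_alines` mm per column, axially `axial_depth_mm /
axial_px` mm per row (defaults 12 mm / 2048 and 3 mm / 512).

The choroid is the band between the bottom edge of the retinal pigment
epithelium (RPE) band and the choroid–sclera interface. Within it, vessel
interiors (lumen) are hyporeflective and stroma hyperreflective. The
pipeline estimates, per macular ring,

$$\mathrm{LV},\ \mathrm{SV},\ \mathrm{TCV} = \mathrm{LV}+\mathrm{SV},
\qquad \mathrm{CVI} = \mathrm{LV}/\mathrm{TCV}.$$

**Polar integration.** Each semi-meridian represents an angular sector
$\Delta\theta = \pi / n_\mathrm{radials}$. With $r(c) = |c - c_\mathrm{fovea}|
\cdot \Delta r$ and $\Delta r$ the (magnification-corrected) lateral pitch,
a column contributes $h_X(c)\, r(c)\, \Delta r\, \Delta\theta$ to compartment
$X$, where $h_X(c)$ is its compartment pixel count times the axial pitch.
The fovea column has $r = 0$ and contributes nothing. A column belongs to
the ring whose radius interval (half-open, `inner/2 <= r < outer/2`,
diameters per the ETDRS convention) contains $r(c)$; the 0–3 and 3–6 mm
rings therefore partition the 0–6 mm disc exactly, and `LV + SV = TCV` and
ring additivity hold to machine precision for any input masks. For a
uniform band of thickness $t$ the rule converges to $\pi R^2 t$; at the
full acquisition geometry the discretization error of the 0–6 mm disc is
about 0.2% (the acceptance script recomputes this).

**Magnification.** Lateral distances scale with the eye's axial length.
Bennett's relation $q(\mathrm{AL}) = 0.01306(\mathrm{AL} - 1.82)$ enters as
the ratio $q(\mathrm{AL})/q(\mathrm{AL_{ref}})$ against a 24.46 mm
reference eye, so the device constant cancels and an emmetropic-reference
eye has scale exactly 1. Axial pitch is unaffected. CVI, a ratio, is
invariant to this scale; volumes are not.

## Boundary detection

All boundary searches are dynamic-programming minimum-cost paths,
column-monotone with slope bound ±2 px/column and deterministic
tie-breaking toward the smaller row. This replaces the learning-based
segmentation used in clinical pipelines, for which no trained weights are
distributable; externally produced boundaries can be injected through
`use_external_boundaries()` and flow through the identical downstream path.

* **RPE**: minimum-cost path through the negative axially smoothed (3 px)
  intensity — the brightest continuous band.
* **Flattening**: integer per-column shifts placing the detected RPE on its
  median row. Shifts are integers deliberately: flattening is then a pure
  pixel permutation per column, preserving the intensity statistics that
  the threshold stage consumes. Flattening twice is the identity.
* **Upper choroid boundary**: the RPE band's bottom edge. The band runs
  parallel to the RPE curve and its thickness is anatomically near
  constant, so the bottom-edge offset is estimated once per image as the
  offset (0–12 px below the RPE) maximizing the column-averaged
  bright-to-dark transition. A per-column maximum-gradient search was
  rejected: vessels abutting the band capture it (this and the choices
  below were selected on ground-truthed phantoms). Whether this edge is
  Bruch's membrane or the RPE inner edge is not resolvable at this
  resolution; the package defines the choroid to start at the band's
  bottom edge.
* **Lower choroid boundary** (choroid–sclera interface): a purely local
  bright-to-dark gradient cost fails in a characteristic way — large
  vessels lying on the interface present a stronger stroma-to-lumen edge a
  few pixels above it, and the path dips across vessel tops. The cost is
  therefore an interface score on a laterally smoothed image (boxcar,
  31 px, wider than a vessel cross-section): mean intensity over 3 rows
  above minus mean over 9 rows below, peaking where a bright band sits on
  *sustained* darkness. Lateral smoothing at a fixed row blurs the
  undulating boundary and biases the path shallow, so a second pass
  re-estimates the score in a boundary-aligned frame (columns shifted onto
  the first-pass path) where the blur vanishes, followed by a median
  filter and slope-limited projection to restore continuity. The lower
  boundary is constrained at least `min_thickness_px = 5` below the upper
  one, preventing collapse onto the RPE under noise; if no appreciable
  transition exists below the upper edge (mean interface score under 5% of
  the RPE edge strength — an effectively absent band), the boundaries are
  returned coincident.

## Binarization

Niblack's local threshold $T(x) = m(x) + k\,s(x)$ with windowed mean $m$
and *population* standard deviation $s$, square window of half-width
`window_radius_px = 15` (31×31) and $k = -0.2$ — the parameterization in
common use for choroidal binarization. Windows are clipped at image
borders (statistics over in-image pixels only; no synthetic padding), and
pixels at exactly the threshold are luminal, so the degenerate
constant-image case classifies everything as lumen — a documented tie-rule
consequence, not an error. The implementation uses summed-area tables; on
integer-valued images (all 8/16-bit OCT data) every windowed sum is an
exact integer below $2^{53}$, so the optimized path agrees *bit-exactly*
with a brute-force per-pixel loop, which the test suite and acceptance
script verify on seeded random images.

Two defaults depart from the plain whole-image recipe, both adopted after
phantom validation and both reversible by argument:

* **ROI-restricted statistics** (`roi_only = TRUE`): windows near the band
  borders otherwise mix vitreous or sub-scleral background into $m$ and
  $s$, dragging the threshold below the luminal level and misclassifying
  boundary-adjacent lumen as stroma. The threshold should describe
  choroidal tissue, not the image around it.
* **Despeckle** (`despeckle = TRUE`): a single 3×3 median before
  thresholding and classification. Speckle is multiplicative and
  heavy-tailed; at 4-look severity the two compartments' intensity
  distributions overlap so strongly that pixelwise classification
  attenuates extreme vascularity fractions toward the middle. The median
  is edge-preserving, so compartment identity survives where a mean filter
  would mix classes (a masked local-mean variant was tried and discarded
  for exactly that failure). Residual attenuation at extreme fractions
  remains the dominant error term of the pipeline.

No contrast normalization is applied before thresholding.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds, per radial: a retina band with a foveal
surface dip, a 4 px hyperreflective RPE band, a choroid band between
smooth band-limited boundaries (mean thickness 0.30 mm, undulation
amplitude 0.05 mm), elliptical luminal blobs (semi-axes 2–7 px, laterally
elongated, matching 50–300 µm vessel cross-sections at the default pitch)
placed at uniform random centres until the target luminal fraction is
reached (default 0.59; the realized global fraction is recorded and stays
within ±0.03), a per-scan linear tilt (uniform within ±5° by default,
recorded as the per-column integer shift), and unit-mean multiplicative
gamma speckle with `speckle_looks = 4` — the first-order model of speckle
in a frame-averaged B-scan; `Inf` disables noise. Intensities are
quantized to 8 or 16 bits. Identical seeds give bit-identical phantoms.

Levels (stroma 170, lumen 40, RPE 230, background 12 at 8 bit) are free
parameters chosen for OCT-like contrast; no public intensity statistics
exist for the instrument class, so accuracy results should be read as a
function of contrast and noise, not as a calibration against one device.

Ground truth records every boundary curve, the lumen mask and the tilt
shift in post-tilt coordinates, and `truth_volumes()` integrates the truth
masks with *the same* polar rule as the pipeline — the quantification
oracle — while the closed-form disc volume provides an independent
analytic check of that rule itself.

Not emulated: signal attenuation with depth and vessel shadowing, motion
artifacts, the bright sclera below the interface, choriocapillaris-scale
structure, pathology. Passing phantom tests therefore demonstrates the
correctness and internal accuracy of the chain, not clinical performance
on real scans.

## Statistics

The study design is within-subject: each subject is measured under control
and hyperglycemia at baseline, after dark adaptation, and 30 s / 2 min /
5 min after return to ambient light. The report estimates, per parameter,
ring and post-baseline timepoint, the difference (glucose − control) of
change-from-baseline — baseline rows carry the raw between-condition
difference instead, and the change convention is the only reading that
makes a "parameters change" grid coherent with baseline tables.

Per-subject differencing absorbs the subject random intercept exactly, so
the mixed-model condition effect for this design equals a covariate-
adjusted analysis of the paired differences: `diff ~ 1 + AL_c + age_c`
with mean-centred covariates, the intercept as the adjusted mean
difference, and a t-based two-sided p on `n − 1 − p` degrees of freedom.
With no covariates this reduces *exactly* to the paired t-test (asserted
to 1e−12 in the tests). Constant or collinear covariates fall back to the
unadjusted analysis with a warning; zero-variance differences report
p = 1 (zero mean) or a degenerate p = 0. Subjects missing a required
session are dropped with a warning; fewer than `p + 2` complete pairs is
an estimation error, surfaced as an empty cell in the report. No
multiple-testing correction is applied by default (matching common
practice in this literature); Holm is available via `p_adjust = "holm"`.

`simulate_cohort()` generates measurement-level cohorts for calibration:
subject baseline means at the scale of a healthy adult macular choroid
(TCV ≈ 26 mm³, CVI ≈ 58.8%), a mild axial-length slope so the adjustment
has something real to absorb, and independent Gaussian session noise per
parameter with SDs set so paired-difference standard errors sit at the
reported scale of such studies (e.g. ≈ 0.09 percentage points for dark
CVI with 24 subjects). Parameters are simulated independently — the
generator targets the exact sampling model of the paired t statistics, for
which normality matters; compartment-coherent values (LV + SV = TCV) come
from the image-level path in `run_study()`, which drives phantom
generation per session and quantifies through the full pipeline.

## Validation problem sizes and tolerances

Phantom-based validation runs at a reduced geometry of 512 A-lines × 192
rows over the same 12 × 3 mm field (the physical pixel pitch scales, so
volumes are comparable); the analytic disc-volume check runs at the full
2048 × 512 geometry. The acceptance script sweeps 20 phantoms with true
luminal fractions 0.45–0.70 at 4-look speckle for recovery bias and RMSE,
3 noiseless phantoms, 500 null cohorts of 24 subjects for the starred-cell
rate at α = 0.05, and 60 cohorts with a −0.36 percentage-point dark CVI
effect for detection. Numerical conventions worth knowing: pixel rows and
columns are 1-based; the ROI spans rows `ceil(upper) <= r < lower`; ring
intervals are half-open; volume partition identities are exact by
construction, so their tests assert machine precision (1e−9 mm³ or
tighter).

## Known limitations

* TCV is systematically underestimated by roughly the boundary error times
  the band perimeter (the interface search trims 1–3 px of band thickness
  under speckle); CVI, a ratio, is far more stable — consistent with why
  the field prefers CVI over thickness metrics.
* Residual CVI attenuation at extreme luminal fractions under heavy
  speckle (see Binarization); the despeckle and ROI options bound but do
  not eliminate it.
* The upper-boundary offset is estimated per image, assuming a
  near-constant RPE band thickness; grossly irregular bands (drusen,
  detachments) violate this and are out of scope.
* The lower-boundary search assumes the region below the interface is
  darker than the band; a bright imaged sclera would require a different
  cost design.
* Fovea position is consumed from metadata, as in the clinical protocol
  (manual marking); it is not estimated from the images.
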