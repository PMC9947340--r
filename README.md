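# choroquant

Volumetric choroidal vascularity quantification from radial swept-source OCT
(SS-OCT) B-scan sets, with a ground-truthed synthetic phantom generator and
paired-design statistics for dark/light-adaptation studies under an acute
glucose challenge.

## The problem

The choroid — the vascular layer between retina and sclera — supplies the
photoreceptors, and its perfusion responds within minutes to light adaptation
and to metabolic challenges such as acute hyperglycemia. Choroidal thickness
alone confounds vessel caliber with stromal swelling. The **choroidal
vascularity index (CVI)** separates the two: on OCT the vessel interiors
(lumen) are hyporeflective and the connective stroma hyperreflective, so a
local binarization splits the choroid into the two compartments and

```
CVI = LV / TCV,      TCV = LV + SV
```

with LV, SV, TCV the luminal, stromal and total choroidal volumes (mm³)
integrated over macular rings (0–3, 3–6, 0–6 mm diameter around the fovea).

`choroquant` implements the full analysis chain for radial scan sets
(default: 18 radial B-scans at 10° steps, 12 mm wide, 2048 A-lines, 3 mm
depth):

1. **RPE detection** — minimum-cost continuous path through the brightest
   axially smoothed band (dynamic programming, slope ≤ 2 px/column).
2. **Flattening** — integer per-column shifts placing the retinal pigment
   epithelium on one row, removing acquisition tilt.
3. **Choroid delineation** — the upper boundary at the RPE band's bottom
   edge; the lower boundary (choroid–sclera interface) by a minimum-cost
   path through a vessel-suppressed interface score, refined in a
   boundary-aligned second pass. External boundaries (e.g. from a
   learning-based segmentation) can be injected instead.
4. **Niblack binarization** — local threshold `T = m + k·s` (31×31 window,
   k = −0.2) with ROI-restricted windowed statistics and a 3×3 median
   despeckle; dark pixels are lumen.
5. **Polar volumetrics** — each semi-meridian is an angular sector of width
   π/n_radials; column thickness integrates as `h(c)·r(c)·Δr·Δθ` into ring
   volumes, with lateral magnification corrected by Bennett's formula
   `q(AL) = 0.01306·(AL − 1.82)` as the ratio against a 24.46 mm reference
   eye.
6. **Adaptation statistics** — per-subject paired differences
   (hyperglycemia − control) of change-from-baseline, covariate-adjusted
   (axial length, age) mean ± SE with t-based p-values, plus
   within-condition paired tests, formatted as the standard reporting grid.

Because no clinical images ship with the package, a **phantom generator**
(`generate_phantom()`) emulates the acquisition — hyperreflective RPE band,
choroid band with elliptical luminal blobs at a controlled true luminal
fraction, per-scan tilt, multiplicative gamma speckle — with complete ground
truth for every stage.

## Worked example

```r
library(choroquant)

g  <- scan_geometry(n_alines = 512L, axial_px = 192L)   # 12 x 3 mm field
ph <- generate_phantom(phantom_params(geometry = g, seed = 7,
                                      target_luminal_fraction = 0.59))
q  <- quantify_session(ph$set)
print(q)
#> Choroidal quantification: subject phantom, control / baseline (lateral scale 1.0000)
#> Regional choroidal volumes (lateral scale 1)
#>  ring LV_mm3 SV_mm3 TCV_mm3 CVI_pct
#>   0-3  1.122  0.782   1.904   58.94
#>   3-6  3.196  2.450   5.646   56.60
#>   0-6  4.318  3.232   7.550   57.19

truth_volumes(ph$truth, ph$set)$CVI[3]   # ground truth: 0.5843454
```

The phantom's true 0–6 mm CVI is 58.43%; the full pipeline recovers 57.19%
under 4-look speckle (the boundary search loses a little band thickness, so
TCV runs ~10% below truth while the lumen/stroma ratio stays within ~0.02). `run_study()` simulates an entire 2-condition ×
5-timepoint adaptation study at the image level and emits the
difference-report grid; `simulate_cohort()` + `build_report()` do the same
at the measurement level for statistical calibration.

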