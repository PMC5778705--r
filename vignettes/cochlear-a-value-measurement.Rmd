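---
title: "Automated A-value measurement by atlas registration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated A-value measurement by atlas registration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochmetric)
```

## The measurement problem

The cochlear duct length (CDL) varies substantially between people, and that
variation matters for cochlear implantation: an electrode array that is too
long cannot be fully inserted, one that is too short leaves the apical
cochlea uncovered, and post-operative frequency mapping depends on where
along the duct each contact sits. CDL is rarely measured directly. The
standard clinical proxy is the **A-value**: the straight-line distance from
the middle of the round window, through the modiolar axis, to the furthest
point of the basal turn. Linear regressions of the form
$\mathrm{CDL} = a \cdot A + b$ then convert the A-value into a duct-length
estimate at the lateral wall or at the Organ of Corti.

Measuring A by hand on clinical CT requires choosing an oblique
reconstruction plane and clicking two landmarks on a low-resolution, noisy
image; inter- and intra-observer variability is substantial, and experts
systematically underestimate. `cochmetric` replaces the manual procedure
with atlas-based registration: a high-resolution reference image (the
atlas) carries expert-placed fiducials once; for each new scan the atlas is
deformably registered to the scan and the fiducials ride along. The
A-value becomes the distance between the two propagated points — no plane
selection, no per-case clicking beyond four coarse initialization
landmarks.

## The registration cascade

The atlas-to-target mapping is estimated in three stages of increasing
flexibility, each initialized by the previous one:

1. **Landmark rigid fit (6 DOF).** Four anatomical landmarks — cochlear
   apex, modiolus, round window, oval window — are placed on the target.
   The closed-form least-squares rigid transform (SVD/Kabsch solution,
   rotation + translation, no scaling) aligns the atlas landmarks to them.
   This only needs to bring the images into the same spatial region.
2. **Affine refinement (12 DOF).** Translation, rotation, scaling and
   shearing in each axis, maximizing normalized cross-correlation (NCC)
   over a sparse random sample (0.1% by default) of voxel centers. The
   affine stage absorbs the global size difference between cochleae —
   which is most of what the A-value measures.
3. **B-spline free-form deformation (64 control points).** A 4×4×4 mesh of
   control-point displacements, interpolated by tensor-product cubic
   B-splines into a C²-smooth dense deformation, captures residual local
   shape differences. We follow the registration literature in quoting the
   mesh's degrees of freedom as the number of control points (64); the
   scalar parameter count (192 = 3 per control point) is reported
   alongside.

NCC is used throughout because the atlas and target come from different
modalities (micro-CT-like vs clinical-CT-like contrast): NCC is exactly
invariant to positive affine intensity maps, so a global contrast/brightness
difference costs nothing. An optional histogram-matching preprocessing step
(`histogram_match` in the configuration, off by default) is available for
stronger non-linear transfer differences.

### Mapping direction and sampling density

The estimated chain maps **atlas coordinates to target coordinates**, so
propagating fiducials is a direct application of the chain — no numerical
inversion is ever needed for the measurement itself. Metric samples are
therefore drawn in the atlas and probed in the target (trilinear
interpolation) at their mapped positions.

Sampling percentages in the clinical protocol this package automates refer
to the coarse clinical image. Because our sample lives on the (much finer)
atlas grid, the dense B-spline stage samples the atlas ROI on a subgrid
strided to the *target's* voxel density (stride =
`round(target_spacing / atlas_spacing)`): that is 100% of the information
the clinical-resolution image carries, without inflating the point count
with sub-resolution samples. The affine stage keeps the conventional sparse
0.1% random sample of full-resolution voxel centers, drawn deterministically
from the configured seed (default 20180122).

### Optimization

The optimizer is deliberately simple and derivative-light, chosen for
robustness across the modality gap rather than speed-optimality:

* **Affine:** regular-step gradient ascent on NCC with central-difference
  gradients in a scaled parameter space (translation in mm; rotation,
  log-scale and shear scaled by 0.05), over a 3-level Gaussian pyramid
  (smoothing factors 4×, 2×, 1×). The step grows 1.5× on success (capped at
  its start value) and halves on failure; a level stops after
  `max_iterations_affine` (200) iterations or when the improvement stays
  below `convergence_tol` (1e-5) for `convergence_patience` (5) consecutive
  accepted steps. Each pyramid level starts from the better of the carried
  parameters and the identity correction, so the final NCC can never fall
  below the initialization's NCC on the reporting sample. Optional
  multi-start (`n_starts`) adds small seeded perturbation starts; the
  default is a single start because the landmark initialization already
  places the optimum inside the capture range.
* **B-spline:** projected gradient ascent using the *analytic* NCC gradient
  with respect to the control displacements (chain rule through the
  trilinear target interpolation and the spline basis). With 192 scalar
  parameters, central differences would cost ~384 metric evaluations per
  iteration for no accuracy benefit. Displacements are clamped per axis to
  `displacement_cap_factor` (0.4) × control spacing, which keeps the
  deformation comfortably away from folding.

Both stages only ever accept improving steps, and the pipeline additionally
evaluates all three stages on one common dense sample, reverting a stage to
its initialization in the (rare) event that it degrades that common metric.
`stage_metrics` in an `a_value_result` is therefore non-decreasing by
construction — the cascade property one expects from a coarse-to-fine
registration.

Everything is deterministic: the same inputs and configuration (including
`rng_seed`) produce bitwise-identical transforms.

### Geometry conventions

All world coordinates are LPS millimetres; voxel indices are 0-based with
the voxel-center convention; NIfTI's RAS frame and Slicer FCSV fiducials
(RAS) are converted on read. ROIs are axis-aligned world-space boxes so the
same ROI applies across resolutions. The target ROI defaults to a 10 mm
margin box around the four initialization landmarks (`landmark_roi()`),
since cropping margins are a user choice rather than a principled constant.
Atlas mirroring for laterality reflects about the volume's own center plane
(an isometry, so the atlas A-value is preserved exactly); the mirror normal
is a grid axis.

## CDL equations are configuration, not constants

Published A-to-CDL regressions (e.g. the Alexiades and Koch relations at
the lateral wall and Organ of Corti) are linear with positive slope. This
package deliberately ships **no built-in coefficients**: the registry
(`register_cdl_equation()`, `load_cdl_equations()`) starts empty and the
example file `inst/extdata/cdl_equations_example.yaml` contains clearly
labelled synthetic placeholders. The packager or user transcribes the
coefficients from the source they intend to rely on, together with its
citation, so the provenance of every clinical number in an output file is
explicit.

## The phantom: ground truth by construction

Clinical validation data cannot ship with a package, so every quantitative
claim here is validated on a synthetic cochlea phantom with analytic ground
truth. The phantom is a logarithmically decaying planar spiral with a
vertical pitch, swept by a constant-radius tube:

$$ c(\varphi) = \big(r(\varphi)\cos\varphi,\; r(\varphi)\sin\varphi,\;
   z_0 + p\,\varphi/2\pi\big), \qquad
   r(\varphi) = R_0\, \delta^{\varphi/2\pi} $$

with defaults $R_0 = 4$ mm, decay $\delta = 0.75$ per turn, tube radius
0.65 mm, pitch $p = 1.8$ mm/turn and 2.5 turns — a human-scale cochlea with
a closed-form A-value of `r round(phantom_true_a_value(phantom_spec()), 3)`
mm, since the round-window fiducial sits on the outer wall at the spiral
start and the basal-turn fiducial on the outer wall half a turn across:

$$ A = \sqrt{\big(R_0 + r(\pi) + 2 r_{tube}\big)^2 + (p/2)^2}. $$

Fiducials are placed on the continuous geometry *before* voxelization, so
`compute_a_value()` on the generated fiducial set equals the analytic value
exactly, independent of any grid.

The atlas-like rendering uses a 0.1 mm / 128³ grid with light blur
(0.25 mm FWHM) and noise (SD 0.02 of the tube intensity); the clinical-like
rendering (`make_target()`) resamples through a deformation onto a
0.6 mm / 64³ grid and degrades it with extra blur (0.7 mm FWHM), a linear
CT-number-like intensity transfer and noise. These stand in for the ~20 µm
micro-CT and ~600 µm clinical CT of the real workflow at desk-scale
runtimes. Simulated inter-specimen variation draws per-axis scaling in
0.9–1.1, rotation up to 10° about a random axis, translation up to 5 mm,
and a smooth random B-spline field of up to 2 mm — the scale of anatomy
differences the affine stage must absorb plus local shape change for the
FFD stage.

**What the phantom does not emulate:** real scala geometry (the duct is a
single tube, not scala tympani/vestibuli), surrounding temporal-bone
anatomy and its confounding structures, CT physics (beam hardening, metal
artifacts, non-Gaussian noise), and landmark placement error (phantom
landmarks are exact; clinical landmarks are hand-placed). Passing the
phantom suite therefore demonstrates that the algorithm recovers known
deformations under modality-gap and noise conditions — it does not replace
clinical validation on real scans.

## Agreement statistics

`evaluate_agreement()` reproduces the standard battery for method-vs-gold
comparison of A-values: absolute percentage difference (mean ± SD),
Shapiro–Wilk normality gate on the differences (delegated to `stats`),
Wilcoxon matched-pairs signed-rank test, Spearman rank correlation, and
Bland–Altman analysis with the ±1.05 mm clinical acceptance band derived
from revised CDL-equation sensitivity.

Choices the literature leaves open, made explicit here:

* **Wilcoxon zeros:** dropped by default (Wilcoxon's original procedure),
  with Pratt's method available (`zero_method = "pratt"`). Exact p-values
  are computed for n ≤ 12 by dynamic programming over all $2^n$ sign
  patterns (valid with mid-ranked ties); larger n uses the tie-corrected
  normal approximation with continuity correction. Two-sided throughout.
* **Spearman:** Pearson correlation of mid-ranks; exact permutation p for
  n ≤ 8, t-approximation otherwise.
* **Bland–Altman:** sample (n−1) SD; limits of agreement mean ± 1.96 SD;
  `frac_outside_clinical` is the proportion of |differences| exceeding the
  band.
* Significance labels in reports use ns at 0.05 and ** at 0.01.

## Worked example

A compact end-to-end run on a reduced phantom (64³ atlas at 0.2 mm — the
full-size defaults are used in the package's validation suite; these sizes
keep the vignette quick):

```{r example, eval = FALSE}
ph <- generate_phantom(phantom_spec(grid_shape = c(64, 64, 64),
                                    spacing = c(0.2, 0.2, 0.2)))
atlas <- atlas_bundle(
  ph$volume,
  subset_fiducials(ph$fiducials, c("round_window", "basal_turn")),
  subset_fiducials(ph$fiducials,
                   c("apex", "modiolus", "round_window", "oval_window")),
  laterality = "right")

chain <- sample_deformation(deformation_spec(seed = 7),
                            volume_extent_roi(ph$volume))
tg <- make_target(ph$volume, ph$fiducials, chain)

res <- measure_a_value(
  atlas, tg$volume,
  subset_fiducials(tg$fiducials,
                   c("apex", "modiolus", "round_window", "oval_window")))
res$a_value     # measured A-value, mm
tg$true_a_value # analytic truth for this deformation
```

## Numerical notes and limitations

* Trilinear interpolation is used for all metric sampling; cubic B-spline
  basis functions only define the FFD displacement. Intensities are held
  as doubles regardless of on-disk type.
* The B-spline support domain requires a full 4×4×4 control neighbourhood;
  the control grid is built to cover the initialization-mapped atlas ROI
  with a small margin, and a fiducial mapped outside the support raises an
  error rather than extrapolating.
* `crop_to_roi()` implements the exact voxel-centers-inside-ROI contract
  for axis-aligned direction matrices; oblique grids fall back to the
  minimal index bounding box of qualifying centers.
* Chain inversion (needed only by the phantom renderer, never by the
  measurement) uses fixed-point iteration and assumes the non-rigid part is
  a bounded perturbation — guaranteed by the displacement cap.
* The optimizer is local: a grossly wrong landmark initialization (e.g.
  landmarks on the wrong ear) is outside the capture range and will
  surface as a low final NCC. Results whose final NCC falls below
  `ncc_floor` (0.3) carry a low-confidence flag.
* Only single-atlas workflows are supported; atlas selection across a
  library of candidates is out of scope, as are DICOM series reading,
  automatic landmark detection and laterality detection.
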