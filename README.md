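# cochmetric

Automated measurement of the cochlear **A-value** — and the cochlear duct
length (CDL) estimates derived from it — from 3D CT volumes, by atlas-based
image registration.

## Why

Cochlear implant electrode selection and post-operative frequency mapping
depend on the cochlear duct length, which varies widely between patients.
Clinically, CDL is estimated from the A-value: the straight-line distance
from the middle of the round window, through the modiolar axis, to the
furthest point of the basal turn, converted by linear regressions
`CDL = a·A + b` (fitted at the lateral wall or the Organ of Corti).
Measuring A by hand on clinical CT is noisy and systematically biased:
experts must pick an oblique reconstruction plane and click two landmarks
on a low-resolution image.

`cochmetric` automates the measurement. A high-resolution atlas image
carries expert-placed fiducials once; for each new scan the atlas is
registered to the scan through a three-stage cascade and the fiducials are
propagated through the recovered transform chain:

| stage | transform | DOF | objective | sampling |
|---|---|---|---|---|
| landmark | rigid (closed-form least squares) | 6 | landmark SSD | 4 fiducials |
| affine | translation+rotation+scale+shear | 12 | NCC | 0.1% random |
| B-spline | 4×4×4 free-form deformation mesh | 64 control points | NCC | dense (clinical voxel density) |

The A-value is the Euclidean distance between the propagated round-window
and basal-turn fiducials. Normalized cross-correlation (NCC) makes the
metric invariant to the micro-CT vs clinical-CT contrast gap; per-stage NCC
is reported and non-decreasing by construction.

The package is for researchers in cochlear morphometry and image-guided
otology: it ships volume I/O (NIfTI / NRRD / MetaImage), fiducial I/O
(CSV and 3D Slicer FCSV), laterality handling by atlas mirroring, a
synthetic cochlea-phantom generator with closed-form ground truth for
validation, and the agreement-statistics battery used to compare a method
against gold-standard measurements (absolute percentage difference,
Shapiro–Wilk, Wilcoxon matched pairs, Spearman, Bland–Altman with a
±1.05 mm clinical acceptance band).

## Worked example

Generate an atlas-like phantom (0.1 mm / 128³ spiral-tube cochlea with
known geometry), render a deformed clinical-like target (0.6 mm / 64³,
random affine + smooth non-rigid deformation, modality-gap blur and noise),
and measure it:

```r
library(cochmetric)

ph <- generate_phantom(phantom_spec())
atlas <- atlas_bundle(
  ph$volume,
  subset_fiducials(ph$fiducials, c("round_window", "basal_turn")),
  subset_fiducials(ph$fiducials,
                   c("apex", "modiolus", "round_window", "oval_window")),
  laterality = "right")

chain <- sample_deformation(deformation_spec(seed = 7),
                            volume_extent_roi(ph$volume))
tg <- make_target(ph$volume, ph$fiducials, chain, seed = 7)

res <- measure_a_value(
  atlas, tg$volume,
  subset_fiducials(tg$fiducials,
                   c("apex", "modiolus", "round_window", "oval_window")))
res
#> <a_value_result> A-value 9.91 mm
#> stage NCC: landmark 0.8346 -> affine 0.9044 -> bspline 0.9115
round(tg$true_a_value, 4)
#> [1] 9.8738
```

The atlas cochlea has A = 8.81 mm; the sampled deformation enlarged it to a
true A of 9.87 mm, and the pipeline measured 9.91 mm — an error of 0.04 mm,
well inside the ±1.05 mm band considered clinically acceptable. The stage
NCC trace shows the cascade at work: the landmark fit roughly aligns
(0.835), the affine absorbs the size change (0.904), the B-spline refines
local shape (0.912).

CDL estimates are produced from user-configured equations (the package
ships no regression coefficients — transcribe them from the published
source you rely on, see `?cdl_equation` and
`inst/extdata/cdl_equations_example.yaml`):

```r
eq <- cdl_equation("my_lateral_wall", slope = 4.2, intercept = -4.0,
                   site = "lateral_wall", source = "<your citation>")
estimate_cdl(res$a_value, eq)
```

A thin command-line front end is installed at
`system.file("cli", "cochmetric", package = "cochmetric")` with
`measure`, `register`, `simulate` and `evaluate` subcommands.

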