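# zharpstrain

Three-dimensional regional myocardial strain analysis from z-encoded tagged
(zHARP-style) cardiac MR, as a tested, reusable R pipeline with a
ground-truthed synthetic phantom.

## The problem

Regional strain from tagged cardiac MR is the reference standard for
quantifying myocardial contractility, but most clinical analyses stop at 1D
(circumferential, `Ecc`) or 2D (`Ecc` + radial `Err`) measures. z-encoded
harmonic-phase imaging adds a through-plane phase encoding to conventional
tagging, so ordinary short-axis slices yield a full 3D strain tensor at
every pixel. The scientific question this package operationalises: **how
much diagnostic value does the third dimension add** when separating
infarcted and peri-infarct (adjacent) myocardium from healthy tissue?

Because the underlying animal imaging data are not public, the package
supplies its own world: an analytic left-ventricular phantom with a
transmural anteroseptal infarct, complex tagged-image synthesis with exact
ground truth, LGE-like viability volumes, and a segment-level strain sampler
calibrated to published per-class Gaussians.

## The core model

At each pixel, the wrapped spatial gradients of the three harmonic phases
are (up to the encoding matrix) the rows of the inverse deformation
gradient:

    F⁻¹ = ∇ₓ [ φ_h/ω ,  φ_v/ω ,  z_s − φ_z/κ_z ]

with tag frequency ω = 2π/7 mm⁻¹ and z-encode frequency κ_z = 2π/33 rad/mm.
Inverting pixelwise gives the deformation gradient F and the Green–Lagrange
tensor **E = ½(FᵀF − I)**, decomposed into directional strains
(`Ecc`, `Ell`, `Err`; diagonal entries in the local anatomical triad from
the epicardial contour) and principal strains (`E1 ≥ E2 ≥ E3`;
eigenvalues). Segment means at end-systole feed logistic models
(1D `Ecc`; 2D `Ecc`+`Err`; 3D `Ecc`+`Err`+`Ell`; principal `E1`+`E2`+`E3`),
compared by in-sample ROC c-statistics with paired DeLong tests and
Youden-point diagnostic accuracy.

The phantom's deformation is an incompressible-family thick-wall
contraction with calibrated wall compressibility, uniform twist, and a
mid-anchored longitudinal shortening plus an apex-anchored regional descent
deficit; everything is analytic, so ground-truth strain is exact. See the
methods vignette (`vignettes/zharpstrain-methods.Rmd`) for the full model,
the design decisions and the known limitations.

## Worked example

Draw a calibrated healthy-vs-adjacent segment sample and compare the strain
models:

```r
library(zharpstrain)
table <- draw_contrast_sample("adjacent", n_healthy = 200,
                              n_per_time = 100, seed = 1)
report <- run_model_comparison(table, "adjacent")
print(report)
#> Contrast: healthy vs adjacent (200 vs 200 segments)
#> Screened covariates: Ecc, Err, Ell
#>   1D           c-statistic 0.873 (SE 0.018)  accuracy 80%
#>   2D           c-statistic 0.961 (SE 0.010)  accuracy 92%
#>   3D           c-statistic 0.986 (SE 0.004)  accuracy 94%
#>   3D_principal c-statistic 0.967 (SE 0.008)  accuracy 92%
#>   1D vs 2D: diff -0.0884, p = 2.417e-09
#>   1D vs 3D: diff -0.1135, p = 5.488e-12
#>   ...
```

One replicate of the univariate model discriminates adjacent from healthy
segments with a c-statistic of 0.87; adding radial and then longitudinal
strain raises it to 0.96 and 0.99, and the paired DeLong tests show each
increment is significant — the incremental-value pattern the package exists
to quantify.

A full imaging run (synthesis → harmonic phase → tracking → strain →
segmentation → metrics → statistics) is one call:

```r
res <- run_pipeline(list(seed = 7, output_dir = "zharp-run"))
res$global_function      # EDV/ESV/SV/EF + scar percentage
head(res$segment_table)  # per-segment end-systolic strain by class
```

which writes NIfTI volumes, CSV tables, segment-model JSON and a manifest
with per-stage checksums under `zharp-run/`. The same pipeline is scriptable
from a shell via `inst/scripts/zharp-pipeline.R`.

## Acceptance script

`scripts/acceptance.R` recomputes the study's headline quantities from
scratch against the installed package: the mean in-sample c-statistics of
the univariate and multivariate strain models for the adjacent and infarct
contrasts (25 seeded replicates of 200-vs-200 segment draws from the
packaged calibration), and the large-sample calibration means of the
segment sampler. Run it as

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

which writes one JSON object with a numeric `value` (and the problem size
`n`) per target.
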