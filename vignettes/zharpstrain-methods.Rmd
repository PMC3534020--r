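---
title: "Methods: a ground-truthed phantom and analysis pipeline for 3D myocardial strain from z-encoded tagged MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D myocardial strain from z-encoded tagged MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zharpstrain)
```

## What this package does

`zharpstrain` implements, end to end, the quantitative machinery of a 3D
regional myocardial strain study based on z-encoded tagged (zHARP-style)
cardiac MR of an infarcted left ventricle:

1. a **phantom** that synthesises complex tagged image sets (two tag
   orientations × two z-encode polarities), LGE-like viability volumes and
   segment-level strain samples, all with analytic ground truth;
2. **harmonic-phase analysis**: spectral extraction of tag and z-encoded
   phases and Newton tracking of material points;
3. **per-pixel 3D strain**: assembly of the inverse deformation gradient
   from the three phase encodings, Green–Lagrange tensors, directional
   (`Ecc`, `Ell`, `Err`) and principal (`E1 ≥ E2 ≥ E3`) decompositions, and
   segment averaging;
4. **viability segmentation**: FWHM / n-SD infarct delineation on LGE,
   chordwise transmurality with a strict >50% rule, and the
   infarct/adjacent/remote (post-infarct) or equal-division (baseline)
   segment models with cross-slice adjacency propagation;
5. **global function metrics**: disk-summation volumes, ejection fraction,
   chordwise wall thickness, scar percentage;
6. **statistics**: univariate/bivariate/multivariate logistic models of the
   strain measures with in-sample ROC c-statistics, Youden-point diagnostic
   accuracy and paired DeLong tests, quantifying the incremental value of
   1D vs 2D vs 3D strain.

Everything the tests and the acceptance script assert is computed by this
code at run time; no empirical number is stated here that they do not
reproduce.

## The segment-level calibration

The packaged calibration table (`segment_strain_calibration()`) carries, per
tissue class (`healthy` at baseline; `remote`, `adjacent`, `infarct` at the
early ≈ 11-day and late ≈ 1-month post-infarct time points), the Gaussian
mean and SD of six end-systolic strain measures in percent. The sampler
draws each measure independently per cell — the source data publish no
covariance — which is a documented limitation for multivariate targets: the
joint distribution of `(Ecc, Err, Ell)` in real segments is correlated, so
simulated multivariable models see somewhat more complementary information
than perfectly correlated measures would provide. The model-comparison
results reproduce the published c-statistics nonetheless because the
between-class separation, not the within-class correlation, dominates them.

## The phantom

### Geometry

The LV wall is a stack of 9–12 contiguous 8 mm short-axis annuli whose
endo/epicardial radii taper linearly toward the apex (default apical scale
0.6). Tissue extends two slice thicknesses past both ends of the imaged
stack: the basal wall continues toward the valve plane and the apical cap
closes below the last slice, so material moving through the end planes under
longitudinal shortening still carries tag signal. Angles are measured
counterclockwise from the anteroseptal RV attachment point (ARVP).

### Deformation model

In material cylindrical coordinates $(R,\Theta,Z)$ with activation
$s(t)\in[0,1]$ and an in-plane regional contractility field
$\rho(\Theta,Z)$:

$$r^2 = R^2 - \left[R_e^2(1-c^2) + \kappa\,(R^2-R_e^2)\right] s\,\rho,
\qquad \theta = \Theta + \tau Z s,$$
$$z = z_f + (Z-z_f)(1-\lambda_\ell s)
      + \lambda_\ell s\,(1-\rho_{\ell,\mathrm{inf}})\,
        b_\theta^{(\ell)}(\Theta)\,K(Z).$$

* $c$ (endocardial contraction), $\kappa$ (wall compressibility) and
  $\lambda_\ell$ (longitudinal shortening) are solved in closed form so the
  mid-wall end-systolic strains in fully contractile tissue equal the
  healthy calibration targets (−19.6% circumferential, +16.4% radial,
  −21.7% longitudinal). With $\kappa = 0$ the radial map reduces exactly to
  the in-plane-incompressible thick-wall contraction (annulus area conserved
  to <0.1%, verified by test); the calibrated default $\kappa \approx 0.10$
  is required because the measured radial thickening of real myocardium is
  far below what exact in-plane incompressibility would force once the
  circumferential target is fixed.
* **Twist is uniform** ($\tau Z s$, not regionally scaled). Torsion is
  transmitted through the stiff scar as near-rigid rotation; scaling the
  twist by $\rho$ imprints a differential-torsion shear on the border zone
  whose squared contribution to $E_{\Theta\Theta}$ (several percent strain,
  asymmetric between the two flanks) exceeds anything reported in vivo.
* **Longitudinal shortening** is a mid-ventricular-anchored global term plus
  an apex-anchored regional *deficit integral*
  $K(Z)=\int_{z_0}^{Z} b_z(t)\,dt$ that accumulates the local shortening
  deficit through the scar column and persists toward the base — a
  regionally reduced atrioventricular-plane descent. This construction
  keeps the local longitudinal stretch exact
  ($z_Z = 1-\lambda_\ell s\rho_\ell$ inside the scar), makes the
  sector-differential displacement vanish at the apical cap, and keeps the
  through-plane displacement within the unambiguous z-encoding range
  $|w| < \pi/\kappa_z = 16.5$ mm everywhere — three constraints that a naive
  multiplicative map $z = Z(1-\lambda_\ell s \rho)$ cannot satisfy
  simultaneously on a 72 mm stack.
* The z-profiles are piecewise linear with smoothly rounded (C¹, quadratic)
  kinks rather than cubic smoothsteps: a cubic taper has constant third
  derivative, which puts a uniform bias into centred through-slice
  differences at 8 mm spacing, while linear segments are differenced
  exactly.

All partial derivatives are closed-form; a finite-difference oracle verifies
the analytic gradient to 10⁻⁴ at random material points, and ground-truth
tensors are produced by Newton inversion plus analytic differentiation.

### Regional impairment

The infarct occupies a 150° angular span (anterior + anteroseptal, the
territory of a mid-LAD occlusion) from the apex to the slice nearest 60% of
the stack, with 95% transmural depth; this yields a scar of ≈16% of the
myocardial volume on the LGE grid, matching the published scar burden. The
in-plane contractility falls to $\rho_{\mathrm{inf}} = 0.18$ over a 40°
smoothstep border zone; the longitudinal deficit uses its own wider (90°)
taper because long-axis motion is smoothed circumferentially by fiber
continuity. The longitudinal plateau scaling is solved from the pooled
post-infarct longitudinal strain target.

**Calibration outcome.** With these defaults the true segment-averaged
end-systolic `Ecc/Err/Ell` in the remote, adjacent and infarct classes land
within 0.5 pooled SD of the calibration targets for six of the nine cells
and within 0.8 SD for the rest (adjacent `Ecc`, remote `Ecc`, infarct
`Ell`). The residual is structural, not a tuning failure: the endocardial
excursion differential across the border zone (≈4 mm over a ≈15 mm arc)
tilts circumferential material lines radially, and the tilt enters
$E_{\Theta\Theta}$ quadratically with a magnitude that is nearly invariant
to the taper width — widening the border zone lowers the tilt exactly as
fast as it dilutes the contraction deficit. Reproducing every cell at 0.5 SD
would require kinematics that violate displacement continuity. The strict
ordering |infarct| < |adjacent| < |remote| holds for all measures.

### Signal model

Each encoding is the ideal complementary-tagging harmonic
$I(\mathbf x)=A(\mathbf x)\exp(i[\omega q_{\mathrm{dir}}(\mathbf x) \pm
\kappa_z w(\mathbf x)]) + \eta$, where $q$ is the reference position of the
material point imaged at $\mathbf x$ (found by Newton inversion of the
deformation), $w$ its through-plane displacement, $A$ a soft-edged tissue
magnitude (one-pixel partial-volume edge) and $\eta$ complex Gaussian noise
(default SD 5% of tissue magnitude, SNR 20). Tag spacing is 7 mm in two
orthogonal in-plane directions and the z-encode frequency is 2π/33 rad/mm;
40 phases cover the cycle at full scale (reduced dimensions are used in the
test fixtures, stated where they matter). Tag fading and T1 relaxation are
ignored.

## Harmonic-phase analysis

### Filtering: two profiles for two jobs

`extract_harmonic_image()` applies a circularly symmetric window around the
tag frequency. For generic (real-valued, two-sideband) tagged data the
classic guard *radius < |ω|/2* keeps the DC and conjugate peaks out and the
default is a raised cosine at 0.4 |ω|. The synthetic encodings, however, are
complex single-sideband signals with **no** other spectral peak, and the
guard may be lifted (`single_sideband = TRUE`). This matters because the
filter kernel is the strain-limiting point-spread function: at radius
0.4 |ω| its main lobe (≈10 mm) is wider than the wall, and transmural
(radial) strain gradients are smoothed away — we measured radial-strain
biases of 5–15 percentage points. The pipeline therefore uses two profiles:

* **strain maps**: flat-top window, radius 2.5 |ω| with a raised-cosine
  edge (flat fraction 0.9) — nearly no smoothing, noise handled by
  averaging and validity bounds;
* **tracking maps**: radius 1.2 |ω|, flat fraction 0.7 — the Newton tracker
  prefers smoother phase at some resolution cost.

### Phase separation

With the two z-encode polarities, $\varphi_z = \tfrac12\angle(h_+ h_-^*)$ up
to a π ambiguity, resolved by temporal continuity from the previous cardiac
phase (first phase: $|\varphi_z| < \pi/2$); continuity is only carried
through pixels that pass the quality mask at the previous phase, because
background phase is noise. The tag phase is recovered modulo 2π by choosing
the branch of $\tfrac12\angle(h_+h_-)$ consistent with $\angle h_+$.
Polarity swap negates $\varphi_z$ and leaves the tag phase unchanged
(tested). All phase arithmetic uses wrapped differences; no global
unwrapping exists anywhere in the package.

### Tracking

A material point is followed by Newton iteration on the wrapped tag-phase
residual (tolerance 10⁻³ rad, cap 20 iterations, step damped by 0.8 when the
residual grows, per-step jump bounded by half a tag period). The
through-plane position uses the first-order slice-crossing solution
$z^* = z_s + w/(1-\partial w/\partial z)$ with the slope from centred
differences across neighbouring slices, trusted only where both neighbours
carry tissue signal and clamped to ±0.45. Contour landmarks are seeded one
pixel inside the drawn boundary, where the tag phase is reliable.

Mid-ventricular mid-wall trajectories track to <0.5 mm over the full cycle
at SNR 20 (tested). Two caveats are inherent to slice-projective tracking:
at the most basal/apical slices the through-plane excursion makes the
tracked (slice-following) point diverge from the true material point by up
to ≈1.3 mm, and sequential stepping accumulates a small drift; both are
documented rather than hidden.

## Per-pixel strain

The wrapped spatial gradients of $(\varphi_h/\omega,\ \varphi_v/\omega,\
 z_s-\varphi_z/\kappa_z)$ are the rows of $F^{-1}$; in-plane by wrapped
central differences, through-plane by centred differences across adjacent
slices (one-sided at stack ends and wherever a neighbour slice fails the
quality mask). Pixels are invalidated when $|\det F^{-1}|\notin[0.2,5]$ or
any strain component exceeds 100% (non-physical), and the quality mask is
eroded by one pixel to drop partial-volume wall-edge pixels whose filtered
phase extrapolates into the background. $E=\tfrac12(F^TF-I)$ is
symmetrised numerically; directional strains use the local anatomical triad
from the tracked epicardial contour (radial = outward contour normal,
longitudinal = slice normal, circumferential completing the right-handed
triad), and principal strains come from a closed-form symmetric eigenvalue
solver (descending, trace-consistent to 10⁻⁸, near-degenerate pairs
tie-broken toward the radial direction).

End-systole is chosen data-drivenly as the phase maximising |mean `Ecc`|,
and segment averages are arithmetic means over valid pixels (<10 valid
pixels → missing value, logged).

**Recovery.** Against the ground truth decomposed with the *same* contour
basis over the *same* valid pixels, class-pooled segment-mean `Ecc`, `Err`
and `Ell` are recovered within 0.02 absolute strain at SNR 20 (tested; the
observed pooled biases are ≤0.006). Individual border-zone segments on the
slices crossed by the longitudinal taper carry through-plane discretisation
bias up to ≈0.05 in `Ell` — an 8 mm slice spacing cannot represent the
taper's curvature — so the recovery criterion is asserted at the class
level, which is also the level the downstream statistics consume.

## Segmentation conventions

* FWHM threshold = remote mean + half the distance to the maximal
  myocardial intensity; the remote estimate is the lowest-intensity tertile
  (making the published semi-automated method fully automatic), and a
  no-enhancement guard (max ≤ median + 6 robust SD) returns an empty mask.
  Only the largest 6-connected component is kept. The n-SD method enforces
  0 < n < 4.
* 120 chords per slice from the endocardial centroid; transmural strictly
  above 50% occupancy; single-chord gaps in a transmural run are closed;
  two disjoint runs wider than 30° are an error (multi-focal infarcts
  unsupported).
* Post-infarct slices: infarct segment = detected border interval; the
  remainder divides into five (basal/mid) or three (apical) equal arcs
  anchored at the counterclockwise border θ₂ (a convention; the source
  method does not state the anchor), the two arcs flanking the infarct are
  adjacent. Baseline/no-enhancement slices: six (basal/mid) or four
  (apical) equal arcs from the ARVP. Slice levels are equal index thirds
  with remainders assigned basally. Adjacency propagates to segments
  overlapping an infarct segment one slice above or below.

## Statistics

Logistic models are maximum-likelihood fits (IRLS via `stats::glm`) with a
univariate Wald screen at p < 0.05 gating covariates into the multivariable
models; early and late post-infarct rows are pooled. ROC analysis is
in-sample (fit and evaluate on the same rows, matching the source
procedure; no cross-validation), with the c-statistic computed from
midranks (ties ½) and its variance from DeLong placement components, so
paired model contrasts need no resampling. Confidence intervals are
logit-transformed Wald. "Diagnostic accuracy" is operationalised as
accuracy at the Youden-optimal cutoff (the source never defines its rule;
ties break toward higher accuracy, then lower cutoff), so exact
reproduction of published accuracy percentages is not claimed. The AUC
equals an exhaustive pair-count oracle on every tested instance, and the
DeLong test rejects at 5% ± 2% under the null (both tested).

## Reproducibility and scaling

Seeds are mandatory everywhere randomness exists; one global seed fans out
deterministically to per-stage streams, and generators restore the caller's
RNG state. The test fixtures use a scaled-down phantom (64-pixel matrix, 10
slices, 10 phases) whose physical parameters — tag spacing, pixel size,
slice thickness, z-encoding, contractility calibration — match the
full-size defaults; only matrix, slice and phase counts are reduced for
runtime. File outputs use a minimal NIfTI-1 writer (no NIfTI package exists
in the supported toolchain), CSV tables with fixed headers, and JSON for
segment models, reports and the run manifest.

## Known limitations

* The sampler draws strain measures independently within a cell (no
  published covariance).
* Three of nine phantom calibration cells sit at 0.5–0.8 SD from their
  targets for the kinematic-continuity reasons above.
* Segment-level (as opposed to class-level) longitudinal strain recovery is
  limited by slice spacing at the scar's longitudinal border.
* Slice-following tracking error grows with through-plane excursion at the
  stack ends.
* The phantom omits tag fading, T1 recovery, k-space/acquisition physics,
  off-resonance and motion artifacts; a green test establishes the
  analysis, not the acquisition.
* Wall thickness from tracked contours inherits the one-pixel landmark
  inset; thickening differences are preserved, absolute thickness is biased
  low by ≈2 pixels.
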