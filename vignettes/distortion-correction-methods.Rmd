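---
title: "Geometric distortion QA and correction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric distortion QA and correction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridwarp)
```

## The problem

Cartesian 3D MR images (gradient-echo / spin-echo) are geometrically
distorted by two system-dependent mechanisms. Static-field inhomogeneity
(ΔB0) shifts signal along the frequency-encoding (readout) axis only: a
voxel that resonates `ΔB0` Hz off-nominal is mapped to a readout position
displaced by

    Δr_B0 = ΔB0 / (γ̄ · G_readout)

where `γ̄` is the reduced gyromagnetic ratio (42.5774 MHz/T for protons)
and `G_readout` the readout gradient strength. With the field in Hz and the
gradient in mT/m this is metres; e.g. 477.7 Hz at 56.1 mT/m gives 0.2 mm.
Gradient non-linearity (GNL) — the deviation of the spatial-encoding
gradients from their nominal linear profiles — displaces voxels along all
three axes. It is a property of the coil hardware, hence
sequence-independent: the same GNL displacement field applies to every
acquisition on a given scanner, which is what makes a phantom-measured GNL
map transferable to subject images.

The forward model composes the two at the undistorted position `v`:

    v' = v + Δr_tot = v + Δr_B0(v) · e_readout + Δr_GNL(v)

Both effects grow with distance from the magnet isocenter, so sub-millimetre
accuracy requirements (image-guided small-animal radiotherapy plans dose on
a 0.2 mm grid) are threatened even for a mouse-brain-sized volume at high
field.

The package implements the QA workflow around this model: a digital grid
phantom with analytically known lattice landmarks; simulators for residual
shim fields and GNL fields as ground truth; the one-step (1SDC) and
two-step (2SDC) correction pipelines; and landmark / Dice evaluation.

## Conventions that remove ambiguity

* Arrays are stored in scanner (x, y, z) order; voxel `(i, j, k)` (0-based)
  has its **center** at `origin + (i,j,k)·spacing` (mm). VOI boxes are
  half-open (`[c − e/2, c + e/2)`), so adjacent VOIs partition cleanly.
* Encoding roles (which axis is frequency-encoded) are mandatory explicit
  metadata — a JSON sidecar or constructor argument — never inferred from a
  NIfTI header, which does not carry them.
* Field maps are in Hz, and the unit is mandatory metadata; conversion to mm
  refuses anything else rather than guessing between Hz, rad/s and ppm.
* Sign convention: a positive off-resonance displaces signal toward the
  positive readout direction. Acquisition polarity is vendor-dependent, so
  this is a recorded, flippable flag; the distort→correct round-trip tests
  pin the internally consistent choice.
* `distort_volume()` is a first-order inverse warp: the output voxel at `p`
  samples the input at `p − Δr(p)`, with the displacement evaluated at the
  undistorted coordinate. Under this small-displacement convention the
  point model `v' = v + Δr(v)` (used by `distort_landmarks()`) and the image
  warp agree to first order, and correction is its inverse:
  `apply_b0_correction()` / `apply_field()` sample at `p + Δr(p)`.
* Pipelines compose all point mappings of a stage (rigid, dense field,
  readout unwarp) and sample the source image **once** (`compose_warp()`);
  chaining resamplings would compound interpolation blur and phase bias.

## The digital phantom and what it does (not) emulate

`build_phantom_pair()` renders a cubic lattice of 0.7 mm walls at 2.5 mm
gaps (pitch 3.2 mm) in a 22 × 22 × 35.6 mm block: a CT-like image (bright
walls, air gaps) and an MR-like image (bright fluid-filled gaps, dark
walls) on identical physical geometry, plus the analytic lattice-intersection
coordinates as truth landmarks. Wall edges are antialiased over one voxel so
intersections can be localized to a fraction of a voxel; an optional
asymmetric wedge in the central cell mirrors the orientation marker of
physical grid phantoms. Optional Gaussian intensity noise is driven by a
single integer seed.

The simulators deliberately omit MR physics that the correction methods do
not use: relaxation and coil-profile shading, susceptibility fields of
heterogeneous tissue, CT beam hardening, and eddy-current or
phase-encoding (EPI) distortion. Signal loss near strong gradients of ΔB0
is available only as an optional intensity attenuation and is off by
default, since no quantitative model for it is established here. Passing
tests on this phantom therefore demonstrates the geometric machinery —
displacement modelling, unwarping, registration, transfer, evaluation —
not robustness to tissue contrast or artifacts of in vivo data.

Ground-truth fields are polynomial: shim scenarios as combinations of the
shim basis (1, x, y, z, xy, xz, yz, x²−y², z², 3rd-order terms) on
coordinates normalized to [−1, 1] over a reference half-FOV, so every
coefficient reads "Hz at the FOV edge"; GNL as per-axis odd polynomials
`a₃p̂³ + a₅p̂⁵` (mm at the FOV edge), zero at isocenter and monotone with
distance, the shape of real gradient-coil non-linearity. The default
normalization half-FOV is 15 × 15 × 21 mm, a typical small-bore acquisition
FOV; it is part of the field definition and is carried by the config
objects so phantom and subject simulations share one physical field.

Simulated shimming works on a random "rough" field (random shim-basis
coefficients plus an off-center Gaussian bump that the basis cannot
represent): scenario 1 subtracts its first-order least-squares fit,
scenario 2 the fit of all terms up to 3rd order (map-based shimming),
scenario 3 first order plus all second-order terms and z³ (pre-set
higher-order currents). Across seeds, scenario 2 always leaves the smallest
residual — the assertable analog of map-based shimming performing best.

## Registration engine

Rigid registration optimizes 6 pose parameters (Euler angles in degrees,
translation in mm, rotation about the fixed-image center) with L-BFGS-B
through a 3-level anti-aliased image pyramid. The non-rigid step is a cubic
B-spline free-form deformation: control points every 10 mm, optimized under
similarity plus 0.01 × a discrete bending penalty (mean squared second
difference of the control lattice per mm²), capped at 1000 iterations —
deliberately the hyperparameters a practitioner would set in an established
registration package for this task. Gradients of the FFD objective are
analytic; the optimizer is deterministic, so repeated runs are
bit-identical.

Several choices here were forced by the nature of near-binary lattice
images and are worth recording:

* **Similarity.** CT and MR grid images are complementary masks — walls
  bright versus gaps bright — which is *not* a linear intensity
  relationship, so neither SSD nor global correlation can register them
  directly, and a sign-blind squared correlation happily locks onto the
  half-pitch "bright-on-bright" alignment of a periodic lattice. The
  pipelines therefore harmonize contrast first (`harmonize_contrast()`):
  the bright class is found by 2-class Otsu, its support is filled at a
  physical scale larger than the lattice gap, and intensities are inverted
  inside that support. Registration then maximizes *signed* global
  correlation (`1 − r`), with an automatic flip if the inputs are still
  inverted. A histogram NMI is provided as a metric and as a rigid
  similarity; it was not implemented as an FFD objective because, for a
  perfectly periodic lattice, NMI shares the phase ambiguity and the
  harmonized-correlation route is both simpler and sharper.
* **Smoothing.** Trilinear interpolation of near-binary images makes the
  similarity piecewise linear with kinks exactly at zero displacement — the
  optimizer's starting point. A sub-voxel Gaussian pre-blur (σ = 0.8 voxels
  for FFD, 1.2 for rigid) restores usable gradients and reduces the
  interpolation phase bias of the fitted pose; the blur is scaled with the
  pyramid decimation factor for anti-aliasing. Warped outputs are always
  computed from the unsmoothed images.
* **Metric masking.** The FFD similarity can be restricted to the fixed
  (CT) phantom support eroded by 0.8 mm. This keeps the support-boundary
  rim of the harmonized moving image — an artifact of inverting a
  partial-volume edge — out of the metric — without the mask, that rim
  systematically biases the recovered field toward the phantom periphery,
  where the GNL signal is largest.
* **Subsampling.** Any constant-stride subsample of a grid-phantom image
  risks aliasing with the lattice period (a stride of one pitch sees a
  single lattice phase and the metric degenerates); the rigid similarity
  therefore subsamples at irregular spacing.

## The pipelines

**1SDC** registers the distorted MR to CT (crop CT to the MR extent → rigid
→ FFD) and corrects both distortion sources with one deformation. **2SDC**
first converts the acquired field map into a B0 spatial map
(`b0_displacement_map()`) and unwarps the MR along the readout axis — a
pure 1D voxel shift, no Jacobian intensity modulation — then removes the
residual, GNL-dominated distortion by rigid + FFD registration to CT. The
FFD field of that second step is the **phantom displacement map**: a dense
ΔrGNL field stored with explicit frame metadata (which image was fixed, at
what resolution). Stage order is structural: the GNL field is never
estimated before B0 correction.

**Subject transfer** (`run_2sdc_subject()`) replays 2SDC on an independent
image: the subject's own field map (upsampled from its native resolution to
the MR grid) corrects B0; the phantom displacement map — resampled onto the
subject grid — corrects GNL, which is valid precisely because GNL is
sequence-independent; the corrected image is then taken to CT resolution
and rigidly registered to CT for evaluation. A displacement map whose
`frame` metadata is not resolved to the scanner frame is rejected rather
than silently misapplied.

Evaluation mirrors the QA protocol: lattice landmarks are re-detected on
every stage image by correlation with a synthetic intersection template and
separable quadratic peak refinement (`detect_grid_landmarks()`, an
automated stand-in for a single consistent human observer; template support
0.42 × pitch so the windows of the outermost lattice layer stay inside the
phantom), paired to truth **by id, never nearest-neighbour**, and
summarized as median ± SD, maximum, Tukey-1.5×IQR-trimmed maximum (reported
separately, never silently substituted) and the fraction of landmarks
within the 0.2 mm accuracy threshold. Overlap is quantified by the Dice
coefficient of wall segmentations from 3-class Otsu thresholds (two
thresholds per modality) after closing + dilation with a 3D ball element,
restricted to the largest VOI so image background does not contaminate the
darkest MR class.

## Problem sizes and numerical choices

The package's own studies run at the phantom protocol's 0.2 mm isotropic
resolution for simulation, unwarping and evaluation (≈131 × 131 × 199
voxels), with registrations performed on 0.4 mm working copies (≈66 × 66 ×
100) — the scale at which the FFD recovers a 0.5 mm-edge cubic GNL field to
well under 0.1 mm median landmark error while a full pipeline completes in
about a minute on one CPU. The transfer study uses a second, independently
parameterized grid object (22 × 22 × 32 mm, 0.5 mm walls, 2.0 mm gaps) as
its synthetic "subject", with its field map rendered at 0.5 mm and
upsampled, mirroring an in vivo protocol. The subject was sized so that its
lattice spans the region where the GNL field is an order of magnitude above
the ≈0.01 mm landmark-measurement floor; on a mouse-brain-sized object the
true displacements would sit at that floor and no relative-reduction
statement could be resolved. Degenerate inputs error early: constant images
cannot be thresholded or registered, non-positive spacings and unknown
basis terms are rejected, landmarks outside a discrete field's domain are
flagged and excluded, and empty VOI regions are skipped with a warning.

Quadratic three-point peak refinement, half-open VOI boxes, snap-to-center
resampling (identity warps are bit-exact), and the irregular similarity
subsample are the small numerical decisions that keep results deterministic
and reproducible; every pipeline records package version, configuration and
seed in its provenance so a run can be repeated bit-identically.

## Known limitations

* The registration engine is tailored to high-contrast, structure-rich QA
  images. On soft-tissue in vivo data the harmonization step does not
  apply, and a mutual-information objective (not provided for the FFD)
  would be needed; one-step non-rigid correction is known to over-deform
  near strong tissue–air interfaces regardless.
* GNL truth fields are separable odd polynomials; real coil fields have
  cross-terms. The FFD estimator does not assume separability, but the
  recovery accuracies quoted here were measured on separable truths.
* The B0 model covers Cartesian readouts only; EPI/spiral phase-direction
  distortion and eddy currents are out of scope.
* Displacement maps transfer only within the same gradient hardware and
  isocenter placement; the package checks frame metadata but cannot detect
  a physically different scanner.
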