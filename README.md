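# gridwarp

Quality assurance and correction of system-dependent geometric distortion in
Cartesian 3D MR volumes, for preclinical imaging at high field — where
sub-millimetre geometric accuracy decides whether MR images can drive
radiotherapy planning and voxel-wise response assessment.

Two hardware effects dominate. Static-field inhomogeneity (ΔB0) displaces
signal along the frequency-encoding (readout) axis by

    Δr_B0 = ΔB0 / (γ̄ · G_readout)

(γ̄ = 42.5774 MHz/T for protons; 477.7 Hz at G = 56.1 mT/m ↦ 0.2 mm).
Gradient non-linearity (GNL) displaces voxels along all three axes and is a
property of the coil hardware — sequence-independent, so a GNL displacement
field measured once on a grid phantom applies to every image from that
scanner. The forward model is `v' = v + Δr_B0(v)·e_readout + Δr_GNL(v)`.

The package provides:

* a data model for volumes, Hz field maps and mm displacement fields with
  physical geometry and NIfTI-1 I/O (JSON sidecars carry encoding roles and
  units — both mandatory, never guessed);
* a **digital grid phantom** (22 × 22 × 35.6 mm lattice, 0.7 mm walls,
  2.5 mm gaps) rendered as a matched CT-like / MR-like pair with analytic
  lattice-intersection truth landmarks, plus ground-truth simulators for
  residual shim fields (polynomial basis) and GNL fields (odd per-axis
  polynomials) and the forward distortion model;
* field-map **readout unwarping** (`b0_displacement_map()`,
  `apply_b0_correction()`) and nested-VOI displacement statistics;
* **rigid and cubic B-spline FFD registration** (10 mm control spacing,
  bending-energy regularization, analytic gradients, deterministic);
* the **1SDC** pipeline (simultaneous correction by non-rigid registration
  to CT) and the **2SDC** pipeline (unwarp B0 first, then register the
  GNL-dominated residual), including **phantom-to-subject transfer** of the
  GNL displacement map;
* evaluation machinery: sub-voxel lattice landmark detection, landmark
  displacement statistics with a 0.2 mm accuracy threshold, 3-class Otsu
  segmentation, 3D ball morphology, Dice coefficients, JSON/Markdown QA
  reports.

## Worked example

Inject a known distortion into the digital phantom and run the two-step
correction:

```r
library(gridwarp)

geom <- phantom_geometry()
ph   <- build_phantom_pair(geom, spacing = 0.2, noise_sd = 0.02, seed = 1)
grad <- gradient_spec(Gz = 56.1, readout_axis = "z")

shim <- shim_config(c(z2 = 600, x = 100, z3 = 150))  # Hz at the FOV edge
gnl  <- gnl_config(a3 = 0.5)                         # mm at the FOV edge
mr_distorted <- distort_volume(ph$mr, field = shim, grad = grad, gnl = gnl)
fieldmap     <- make_shim_field(shim, ph$mr)

cfg <- pipeline_config(ffd = ffd_model(max_iterations = 500, levels = 3,
                                       stride = 2))
res <- run_2sdc_phantom(mr_distorted, fieldmap, ph$ct, grad, cfg,
                        geom = geom, landmarks = ph$landmarks,
                        region = standard_vois()$VOI3)
res$stats[, c("stage", "median", "fraction_below_threshold")]
#>       stage      median fraction_below_threshold
#> 1     rigid 0.145155814                0.8089054
#> 2        b0 0.136122463                0.8033395
#> 3 corrected 0.007713635                1.0000000
res$dice
#>     rigid        b0 corrected
#> 0.9941478 0.9971443 1.0000000
```

Reading the output: before correction the median lattice-landmark
displacement is 0.145 mm and only ~81% of landmarks sit within the 0.2 mm
accuracy goal; unwarping the B0 term removes the readout-axis shifts; the
FFD step removes the GNL component, leaving a
0.008 mm median residual — every landmark within threshold — while the
wall-segmentation Dice against CT rises stage by stage. `res$field` is the
dense phantom displacement map (ΔrGNL); handing it to
`run_2sdc_subject()` corrects GNL on an independent image acquired with the
same gradients.

A thin CLI over the same functions ships in `inst/scripts/gridwarp.R`
(subcommands `simulate`, `shim-study`, `run-1sdc`, `run-2sdc`,
`run-2sdc-subject`, `evaluate`; NIfTI + JSON-sidecar volumes, CSV
landmarks, YAML configs).

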