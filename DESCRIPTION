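Package: gridwarp
Title: Geometric Distortion QA and Correction for Cartesian MR Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality-assurance and correction toolkit for system-dependent
    geometric distortion in Cartesian 3D magnetic-resonance volumes. Models
    static-field inhomogeneity (B0) displacement along the frequency-encoding
    axis and gradient non-linearity (GNL) displacement along all three axes,
    and implements one-step (non-rigid registration to CT) and two-step
    (field-map unwarping followed by non-rigid registration) correction
    pipelines, phantom-to-subject transfer of GNL displacement fields, and
    landmark/Dice evaluation machinery. Includes a digital twin of a
    3D-printed grid phantom with analytically known lattice landmarks and
    ground-truth distortion simulators, so every correction stage can be
    verified against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
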