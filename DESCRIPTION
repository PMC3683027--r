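Package: lungvent
Title: Dynamic Regional Ventilation Maps from 4D CT of the Rodent Lung
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes voxel-level lung volume-change ("ventilation") maps from
    time-series (4D) CT images of mechanically ventilated rodents. Provides the
    full processing chain: image preparation (filtering, lung masking,
    background saturation, histogram equalization), two-stage affine plus
    B-spline non-rigid registration (or import of externally computed
    displacement fields), finite-element computation of the deformation
    gradient and its Jacobian on a hexahedral voxel-centroid mesh,
    Hounsfield-unit calibrated air-fraction estimation, and the intensity-joint
    regional ventilation estimate. Validation utilities cover landmark target
    registration error with a grid-geometry misregistration rule,
    pressure-volume loop assembly, compliance, and hysteresis area. A digital
    phantom module generates lung-shaped CT test objects deformed by
    closed-form fields with known Jacobians under a tissue-conservation
    intensity model, together with synthetic ventilator traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    tiff,
    Matrix,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
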