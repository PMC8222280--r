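Package: radlung
Title: Dose-Binned Lung Density and Ventilation Response Analysis for Thoracic Radiotherapy Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies radiation-induced change in pulmonary Hounsfield units
    and ventilation from longitudinal CT imaging. Segments contrast-carrying
    vasculature from dynamic contrast-enhanced 4DCT via a maximum-intensity
    projection and a bimodal-histogram threshold, builds 10 Gy isodose-bin
    contours with mirrored contralateral controls, harmonizes fractionation
    schemes through EQD2, measures dose-binned percent HU change in and out of
    vessels, computes Jacobian-determinant ventilation maps and damaged-voxel
    fractions from displacement fields, and correlates a swine cohort's dose
    response against human timepoints. Includes a synthetic thorax phantom
    with ground truth that emulates the statistical structure of the measured
    data, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
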