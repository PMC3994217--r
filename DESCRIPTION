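Package: limbvol
Title: Circumference-Based Limb Volumetry and Drug Dosing for Isolated
    Limb Perfusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models an extremity as a chain of truncated cones (frusta)
    built from tape-measured circumferences at fixed 5-cm levels, computes
    the perfused limb volume with tourniquet-level subtraction, corrects
    the volume by the ideal-to-actual body weight quotient to discount
    obesity-excess fat, and converts the result into a per-liter melphalan
    dose for isolated limb perfusion. Includes a synthetic CT-phantom
    toolkit (voxelized limbs with fat, muscle and bone compartments and
    known analytic volumes), Hounsfield-threshold volumetry, and a
    method-comparison study that replicates the circumference-versus-CT
    validation design on simulated patient cohorts with Pearson
    correlation and Kolmogorov-Smirnov normality statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
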