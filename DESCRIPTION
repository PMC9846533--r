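Package: lsmreg
Title: Cross-Modality Registration of Light-Sheet Microscopy to Magnetic
    Resonance Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Restores the in-skull morphology of distorted light-sheet
    microscopy (LSM) brain volumes by registering them to magnetic resonance
    histology (MRH) of the same specimen.  Provides landmark-based
    initialization (affine or thin-plate spline), staged multi-resolution
    intensity registration (rigid/affine, symmetric B-spline free-form
    deformation, and symmetric diffeomorphic SyN-style matching) driven by
    mutual information, cross-correlation or windowed local
    cross-correlation, fiducial-based root-mean-square (L2) evaluation with
    regional breakdowns, inverse label transfer onto uncorrected volumes,
    and regional volume-ratio morphometry.  A synthetic two-modality brain
    phantom generator with known ground-truth deformation, paired fiducials,
    landmarks and region labels makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
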