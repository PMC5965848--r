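Package: petresp
Title: PET-Based Treatment-Response Analysis for Preclinical Xenograft Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying tumor response to therapy in small-animal
    PET studies. Implements seeded random-walker segmentation of lesions on
    the voxel lattice graph, standardized-uptake-value quantification
    (SUVmax, SUVmean, metabolic tumor volume, total lesion glycolysis or
    proliferation), volume-adapted RECIST response classification from
    caliper measurements (tumor volume response, TVR), and ROC analysis with
    Youden-index cutoff selection for responder discrimination. Includes a
    synthetic phantom and cohort generator with known ground truth for
    end-to-end validation, and NIfTI/DICOM volume I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
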