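Package: slndetect
Title: Computer-Assisted Sentinel Lymph Node Detection in SPECT/CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a computer-assisted workflow for detecting sentinel
    lymph node candidates in paired SPECT/CT volumes: resampling of both
    modalities to a common 1 mm isotropic grid, semi-quantitative background
    suppression of the emission data, hot-spot segmentation by local-maximum
    seeding and recursive 26-neighbour region growing with common-voxel
    deletion, Hounsfield-unit tissue classification of the CT with
    morphological regularisation of bone, rule-based classification of hot
    spots into probability-ranked lists of "true" and "false" lymph-node
    candidates, and the confusion-matrix statistics used to evaluate such a
    reader-assistance system. A deterministic digital phantom generator
    produces paired SPECT/CT volumes with ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
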