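Package: cmtfusion
Title: Coupled Matrix-Tensor Factorization for Simultaneous EEG-fMRI Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint decomposition of a third-order EEG spectrogram tensor and an
    fMRI region-of-interest (ROI) time-series matrix into shared neural sources.
    EEG recordings segmented per fMRI volume are tensorized with Thomson's
    multitaper method into a time x frequency x channel power tensor; the tensor
    and the ROI matrix are then factorized jointly, with the shared temporal
    signatures coupled to the BOLD signal through a hemodynamic response
    function (HRF) basis with ROI-specific coefficients. Model order and the
    stimulus-related component are chosen by an ensemble of randomly initialized
    fits scored with four indicators: core consistency (CORCONDIA),
    reproducibility under graph-structured clustering, similarity to the
    stimulus time course, and permutation-based significance of the spatial
    signature with familywise error control. A synthetic-data module generates
    ground-truth sources, raw EEG, coupled ROI series and gambling-paradigm
    stimulus timecourses so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
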