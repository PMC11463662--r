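Package: LMSFilter
Title: Local Mean Suppression Filtering for Background Identification in
    Fluorescence Images
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the local mean suppression filter (LMSF), a
    nonlinear pixel-wise operator that labels a pixel as background when
    the ratio of its intensity to the mean intensity of its local
    neighbourhood falls below a threshold, and the cumulative multi-scale
    LMSF method that unions single-scale background masks over a set of
    neighbourhood sizes. Includes adaptive no-padding boundary averaging,
    integral-image local means, scale-selection heuristics, multi-channel
    co-localization class maps, pre-segmentation denoising, a
    deterministic synthetic fluorescence-nuclei image generator with
    ground-truth background masks, TIFF/PNG input and output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Software, Preprocessing, Visualization, CellBiology
RoxygenNote: 7.3.3
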