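Package: phasefuse
Title: Integrative Fourier-Mellin Phase Correlation for Multi-Modal Plant
    Image Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns structurally non-identical multi-modal plant images,
    typically a fluorescence (FLU) and a visible-light (VIS) view of the same
    shoot, using Fourier-Mellin phase correlation. Provides preprocessing
    variants (grayscale, color edges, bounding-box cropping, blue-mat
    removal), similarity-transform registration with a peak-height
    reliability gate, a scale-space sweep whose locally optimal per-scale
    registrations are integrated into a single binary plant mask, success
    rate and overlap ratio evaluation metrics, segmentation-via-registration,
    and a seeded synthetic FLU/VIS scene generator with exact ground truth
    for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
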