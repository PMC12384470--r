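Package: ciliarank
Title: Quantification and Rank-Based Scoring of Two-Channel Ciliary
    Immunofluorescence Staining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An automated image-analysis pipeline for two-channel
    immunofluorescence slides of ciliated airway epithelium. Segments
    stained objects independently in a test-antibody (red) channel and a
    stable axoneme-marker (green) channel, computes the headline shape,
    intensity and colocalization parameters (area, eccentricity,
    compactness, intensity mass displacement, directional rank-weighted
    colocalization, centroid distance between paired objects), relates
    red objects to green objects by pixel overlap with a unique-pair
    filter, screens parameters for association with slide storage
    condition, and aggregates per-parameter ranks into a mean-rank
    performance metric for storage conditions and antibodies. Includes a
    synthetic two-channel slide generator with known ground truth that
    emulates storage-induced degradation (loss of ciliary signal with a
    compensating diffuse cytoplasmic signal), so the whole pipeline is
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
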