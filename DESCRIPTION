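Package: tonescale
Title: Reliability and Fairness Auditing of Skin Tone Labeling Schemes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating skin tone labeling schemes used to annotate
    dermatologic image datasets. Implements deterministic sRGB to CIELAB color
    conversion and the individual typology angle (ITA), median pixel-wise color
    extraction from dermoscopy-style image patches, inter-rater reliability
    statistics (linear-weighted Cohen's kappa, two-way random-effects ICC),
    cluster dispersion of subjective scale categories in colorimeter CIELAB
    space (Davies-Bouldin index, mean silhouette with a singleton convention),
    aggregation of crowdsourced ordinal labels under qualification and majority
    rules, and Kolmogorov-Smirnov auditing of classifier score distributions
    across skin tone classes. A seeded synthetic study generator emulates a
    skin-tone-balanced cohort so every analysis stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    ggplot2,
    jsonlite,
    png,
    rlang
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jpeg,
    optparse,
    withr
Config/testthat/edition: 3
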