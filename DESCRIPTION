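Package: wellquant
Title: Quantitative Image Analysis of Micropatterned Pancreatic-Endoderm Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for multi-channel immunofluorescence images of
    micropatterned (microwell-confined) stem-cell-derived pancreatic endoderm
    cultures. Implements equal-area concentric-zone cell density profiling,
    nuclear and nuclear-to-cytoplasmic transcription-factor intensity metrics
    with normalization to an unconfined control, radial F-actin architecture
    classification (uniform, peripheral, central), PDX1-high cell and spatial
    cluster detection in monolayers, and the associated comparison statistics
    (one-way ANOVA with Tukey post-hoc, Student's t-test, imaging-modality
    consistency). Ships a seeded synthetic multi-channel image generator with
    full ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
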