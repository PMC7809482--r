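Package: platequant
Title: Image-Based Quality Control and Morphometrics for Automated
    Cell-Culture Plates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis tools for automated cell-culture and
    high-content screening plates: label-free confluency estimation and
    seeding-homogeneity quality control from transmitted-light well scans,
    serial-dilution linearity checks, a difference-of-Gaussians /
    watershed pipeline for nuclei segmentation, single-cell region-of-
    interest construction and tyrosine-hydroxylase-positive neuron
    calling in three-channel immunofluorescence images, brightfield
    organoid morphometrics (area and Feret's diameter with batch
    coefficient-of-variation statistics), rank-based group comparisons
    (Mann-Whitney, Kruskal-Wallis, Dunn), and cell-expansion capacity
    planning arithmetic. Ships a synthetic-image generator with exact
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    igraph,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
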