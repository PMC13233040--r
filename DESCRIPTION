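Package: mragree
Title: Multireader Agreement Metrics for Object Detection and Instance
    Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Generalizations of the Jaccard and Sorensen indices that measure
    agreement across an arbitrary number of readers annotating objects in 2-D
    images, such as cell nuclei in fluorescence microscopy. Provides the
    consensus-matching machinery (pairwise agreement matrices, thresholded
    non-maximum suppression, cross-reader match matrices, layered consensus
    images), ground-truth curation at any reader-agreement stringency,
    reader-evaluation procedures (leave-one-reader-out analysis,
    algorithm-as-additional-reader comparison with noninferiority bounds,
    stringency curves), readers and writers for label images and instance
    JSON, and a synthetic multi-reader annotation generator for end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
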