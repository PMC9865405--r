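Package: kernelhotspots
Title: Meta-Analysis of QTL and QTN Hotspots for Maize Kernel Size Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrates literature-curated quantitative trait loci (QTLs) and
    quantitative trait nucleotides (QTNs) for the four maize kernel size
    traits (kernel length, kernel width, kernel thickness and hundred-kernel
    weight) into consensus hotspot regions on the B73_V4 reference genome.
    Projects QTLs to physical coordinates via flanking markers, calls
    trait-specific QTL clusters (>= 3 co-localized intervals) and QTN
    clusters (>= 5 variants in a 5 Mb sliding window), merges clusters
    across traits into hotspots (>= 3 co-localized clusters), co-locates
    cloned genes, screens candidate genes by kernel-expression criteria
    (MaxExp/MaxExpKernel ratio and kernel FPKM), and tests Gene Ontology
    term over-representation with a hypergeometric test under
    Benjamini-Hochberg false-discovery-rate control. Ships a synthetic-data
    generator with planted ground truth for end-to-end validation, plus
    curated fixtures of published cloned-gene and hotspot tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
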