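Package: spectragwas
Title: Leaf Reflectance Spectra as Phenotypes for Genome-Wide Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for spectral phenomics in quantitative
    genetics: calibrates relative leaf reflectance from raw radiance scans,
    screens spectra with local-outlier-factor quality control, removes known
    environmental effects with per-wavelength linear models (with sequential
    variance partitioning), computes classical spectral indices, and derives
    data-driven phenotypes by hierarchical spectral clustering with parallel
    analysis (HSC-PA): recursive bipartition of the wavelength set that stops
    where a single principal component suffices, with terminal-segment PC1
    scores used as traits. Native general and mixed linear model association
    scans (EMMA-style REML with P3D), PhenoSpD effective-number-of-tests
    correction from cross-trait LD score regression, Benjamini-Hochberg FDR,
    top-k dynamic-threshold comparison, and candidate-gene windowing from GFF3
    complete the workflow. A multiparent recombinant-inbred-line simulator
    generates genotypes, structured spectra, metadata and a truth record so
    every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
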