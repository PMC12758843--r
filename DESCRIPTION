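Package: photocolony
Title: Structural Color Analysis of Bacterial Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bacterial structural color studies built
    around a Flavobacterium colony photonic model. Simulates and inverts
    angle-resolved reflectance (goniometry): the diffraction grating equation
    recovers the hexagonal lattice period from scattering maps, and the
    Bragg-Snell dispersion relation recovers the effective refractive index
    from specular maps. Also summarizes molybdenum-cofactor pathway gene
    presence/absence by structural-color class, clusters gene loci into
    putative operons by genomic proximity, and implements a thresholded
    differential protein abundance workflow (pooled t-test,
    Benjamini-Hochberg correction, fold-change gating, complete
    repression/induction calls, secretion-likelihood filtering, and
    operon-level regulation overlays). A synthetic-data module generates
    every input with known ground truth so all stages are testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
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
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
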