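Package: nucleochrom
Title: Chromatin Analysis of Multi-Compartment Algal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse chromatin accessibility (ATAC-seq), active
    transcription (KAS-seq) and three-dimensional genome organization (Hi-C)
    in organisms whose cells carry several genomic compartments of distinct
    origin and copy number, such as chlorarachniophyte algae with a nucleus,
    a nucleomorph, a mitochondrion and a plastid. Provides per-position
    unique-mappability tracks and mappability-corrected RPKM, multimapper
    weight normalization, compartment-resolved read partitioning and
    treatment-versus-input enrichment, fragment-length spectra with mode
    detection, TSS metaplots with a simple Poisson peak caller, positioned
    nucleosome (dyad) calling with V-plots, and Hi-C contact-matrix binning
    with vanilla-coverage and Knight-Ruiz balancing, distance-decay,
    trans-contact profiles and telomere-network scores. A fully configurable
    synthetic-data generator emulates a small multi-compartment genome so the
    whole pipeline is testable by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
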