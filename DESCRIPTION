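Package: mipscreen
Title: Design, Simulation and Triage for smMIP Targeted Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A toolkit for targeted genetic screening with single molecule
    molecular inversion probes (smMIPs). Covers probe panel design (tiling
    of target regions into gap-fill windows with flanking extension and
    ligation arms, logistic probe scoring, orderable oligo assembly and
    depth-based pool rebalancing), simulation of capture sequencing with
    unique molecular identifiers, PCR duplication and sequencing error,
    UMI-aware read processing to consensus fragments, a simplified pileup
    genotyper and probe-depth copy-number caller, and a variant-triage
    cascade (CADD and population allele-frequency thresholds, consequence
    classification from HGVS nomenclature, gene-specific rules and
    Mendelian inheritance-mode assembly) with cohort summarisation.
    Ships a 19-gene amelogenesis imperfecta panel fixture and a
    transcribed screening-cohort fixture for worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
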