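Package: hsfkit
Title: Identification, Classification and Expression Profiling of Plant
    Heat Shock Transcription Factor Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide discovery and characterisation of plant
    heat shock transcription factor (Hsf) gene families, with bread wheat
    (Triticum aestivum) as the motivating system. Provides a position-specific
    scoring model screen for candidate Hsfs in a proteome, DNA-binding-domain
    and HR-A/B coiled-coil annotation with insert-length based class A/B/C
    assignment, C-terminal regulatory motif scanners (AHA, NLS, NES, ER
    retention, LFGV) and physico-chemical calculators, neighbor-joining
    phylogeny with Poisson-corrected distances and bootstrap-anchored subclass
    assignment, allohexaploid homeolog-triad detection, intron-exon structure
    derivation from cDNA/genomic pairs, TPM-based treatment-response profiling
    and the 2^-ddCt qRT-PCR calculator. A seedable synthetic-data generator
    with full truth tables makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
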