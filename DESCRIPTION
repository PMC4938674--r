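Package: shoxdel
Title: Deletion Mapping and Copy-Number Genotyping at the Equine SHOX Locus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping large overlapping deletions in the
    pseudoautosomal region around SHOX from short-read sequencing and
    droplet digital PCR data, as used to dissect skeletal atavism in
    Shetland ponies. Implements a pooled-versus-individual fixed
    allele-frequency-difference SNP screen, normalized read-depth
    copy-number analysis in 1-kb windows with control-pool Z-scores,
    deletion segment calling with soft-clip breakpoint refinement and
    tandem-repeat annotation, Poisson-occupancy droplet digital PCR
    copy-number genotyping, and recessive-allele population summaries.
    A synthetic data generator emulating the study's sequencing design
    (individually sequenced cases against an equimolar control pool)
    makes the whole pipeline testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    yaml
Config/testthat/edition: 3
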