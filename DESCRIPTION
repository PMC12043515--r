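Package: relspectra
Title: Comparative Binding Analytics for Transcription-Factor Paralogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the genomic binding and biochemical
    preferences of transcription-factor paralogs, built around the NF-kB
    Rel/RelA system. Implements knockout-dependence classification from
    nascent-transcript RPKMs, differential ChIP-seq occupancy spectra
    (reproducibility filtering, top-N selection, interval merging,
    RPKM-ratio spectra, equal-count binning, promoter annotation and
    ranking), ZOOPS binomial motif enrichment with PWM scanning and de novo
    k-mer discovery, protein-binding-microarray z-score mining,
    dissociation-kinetics fitting (exponential off-rates and half-lives),
    and a clade-restricted diagnostic-residue scanner for paralog
    alignments. Ships seeded synthetic-data generators with planted ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
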