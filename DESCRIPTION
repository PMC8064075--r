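Package: chimerascape
Title: Classification and Landscape Characterization of Chimeric RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates fusion-transcript (chimeric RNA) candidates reported by
    split-read callers such as SOAPfuse against a GTF gene annotation.  Each
    candidate junction is classified three ways: by junction position relative
    to known exon/intron boundaries (E/E, E/M, M/E, M/M), by the locus
    relationship of the parental genes (Read-Through, INTRA-Others, INTERCHR),
    and by the predicted effect on the reading frame of the 3' partner
    (in-frame, frame-shift, NA, or isoform-dependent "both").  Implements the
    M/M exclusion filter used to reduce false discoveries, per-sample and
    cross-sample landscape summaries with Venn-style overlap decomposition and
    Circos link export, qPCR quantification arithmetic (2^-ddCt and
    nuclear/cytoplasmic ratios), junction-flanking sequence extraction for
    primer design, and a deterministic synthetic genome/annotation/call-set
    generator with complete ground-truth labels for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
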