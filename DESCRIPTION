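Package: exo7tseq
Title: Strand-Specific Analysis of Meiotic DSB End Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of nucleotide-resolution, strand-specific
    maps of meiotic double-strand-break (DSB) ends of the Exo7/T-seq /
    S1-seq / END-seq family. Extracts per-base blunted-end counts from
    mapped paired-end alignments, builds co-oriented average profiles
    around DSB hotspot centers with Hanning smoothing, estimates DNA
    end-resection length distributions by background subtraction and
    peak normalization, calls and classifies enrichment peaks against
    PRDM9-directed and default hotspot catalogs, and quantifies signal
    over a pseudoautosomal-like interval. Includes a synthetic-data
    generator with genotype presets (wild type, Ankrd31 mutants, Spo11
    null) so the whole pipeline runs and is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
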