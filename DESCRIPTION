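Package: mitoribo
Title: Mitoribosome Profiling Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analyzing mitochondrial ribosome profiling data from
    aligned footprint reads: UMI deduplication and spike-in normalization,
    per-read-length A-site offset calibration from 3' ends, A-site tracks and
    triplet periodicity, codon-level occupancy and pausing, initiation
    footprint profiles on leaderless mRNAs, quantification of translation
    initiation on processed versus unprocessed bicistronic transcripts,
    genome-wide start-codon scoring for small-ORF nomination, relative
    synthesis quantification with CDS masking and mitonuclear balance
    statistics, and start-codon variant conservation analysis. Includes a
    synthetic-data generator that produces toy genomes, annotations, aligned
    reads, and variant catalogs with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
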