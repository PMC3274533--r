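Package: splicerefine
Title: RNA-Seq Gene-Model Refinement and Alternative-Splicing Discovery for
    Ciliate Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of alignment-level RNA-seq evidence for
    compact, intron-rich genomes such as the Tetrahymena thermophila
    macronucleus. Validates and filters splice-junction evidence (canonical
    GT-AG, anchor length, non-redundant read support), assembles
    coverage-island transcripts, confirms and corrects annotated gene models
    (boundary errors, missing or extra introns, split and fused genes), calls
    novel transcribed regions and UTRs, classifies the four basic classes of
    alternative-splicing events under stringent evidence thresholds with
    intron-retention specificity statistics, quantifies expression (RPKM) with
    stage-specific up-regulation calls, reassigns and renormalizes microarray
    probes against corrected models, and performs GO term enrichment. Includes
    a synthetic-data generator that emulates the statistical structure of the
    ciliate transcriptome (A+T-rich noncoding sequence, short introns,
    ciliate nuclear genetic code) with full truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
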