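Package: regmodes
Title: Integrative Chromatin Accessibility, TF Binding and Expression
    Analysis with Regulatory-Mode Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating ATAC-seq chromatin accessibility,
    transcription-factor ChIP binding and RNA-seq differential expression
    around a nuclear-receptor perturbation. Implements RPKM quantitation,
    low-count filtering, signed and absolute ranking of peaks by
    accessibility change, equal-sized rank binning, per-bin hypergeometric
    motif-enrichment landscapes from log-odds PWM scanning, similarity-based
    motif-family merging, genomic-feature annotation of peaks, cut-site
    footprint aggregation with protection scoring, and classification of
    direct target genes into regulatory modes (ligand-activated,
    ligand-repressed, basally required or repressed but pharmacologically
    nonresponsive). A seeded synthetic-data module generates complete
    ground-truth-annotated inputs (genome, negative-binomial peak counts,
    sequences with planted motifs, binding sites, differential-expression
    tables, cut-site tracks) so every stage runs and is testable at desk
    scale.
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
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Epigenetics, ATACSeq, ChIPSeq, GeneRegulation, MotifAnnotation,
    Sequencing, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
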