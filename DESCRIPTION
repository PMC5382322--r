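Package: EIMRtools
Title: Hormone-Induced Differential ChIP-Seq Binding Regions, Motif
    Enrichment by Resampling, and Chromatin Assay Quantification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing hormone-dependent recruitment of
    chromatin remodellers. Classifies ecdysone-induced binding regions
    (EIMRs) from two-condition ChIP-seq tag lanes using per-million lane
    normalization and an inclusive induction-ratio cutoff; tests motif
    enrichment in region sets against a null built from size-matched
    randomly placed genomic regions with a normal-approximation P value;
    quantifies RT-qPCR experiments by the delta-delta-Ct method and MNase
    protection assays with per-region rescaling; and fits one-phase
    exponential kinetics to restriction-enzyme-accessibility remodelling
    time courses. A deterministic synthetic-data generator emulates all
    required input shapes with recorded ground truth so every analysis
    step can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: ChIPSeq, Epigenetics, MotifAnnotation, Sequencing, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
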