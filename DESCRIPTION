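Package: dendritr
Title: Compartment-Specific Transcriptomics of Neuronal Dendrites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for defining the dendritic transcriptome of
    hippocampal CA1 pyramidal neurons from compartment-specific TRAP-seq,
    PAPERCLIP and FMRP CLIP-seq data. Assembles expressed 3'UTR isoforms
    from filtered polyA-site peaks and splice junctions and classifies
    alternative-polyadenylation events; calls dendrite-present and
    dendrite-enriched mRNAs with a negative-binomial Wald test; tests
    differential 3'UTR isoform usage with a beta-binomial model; computes
    compartment-specific FMRP CLIP scores by regression of CLIP expression
    on TRAP abundance and classifies dendritic FMRP targets by a two-rule
    criterion; quantifies percent-spliced-in from junction reads; estimates
    the cell-body-layer boundary in smFISH images and classifies spots by
    distance; scans 3'UTRs for G-quadruplex motifs; and runs preranked
    gene-set enrichment on CLIP-score rankings. A synthetic-data module
    generates every input with known ground truth so the full pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    MASS,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    fgsea,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
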