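Package: annomerge
Title: Integration of Gene Prediction Sets and Coding-Region Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Combines gene models from independent gene-prediction pipelines
    into consensus loci by single-linkage overlap clustering, with an overlap
    threshold sweep and knee-based threshold selection, homology-evidence
    filtering and representative-model selection. Downstream
    characterization of the merged gene set includes third-codon-position
    nucleotide composition (GC3, CG3-skew, CpG genomic signature, decile
    classes, positional gradients), multinomial and codon-position-periodic
    Markov models of coding sequence, intronless-gene detection with
    taxonomic-sharing classification, and domain-rule classification of
    candidate disease-resistance genes with physical cluster detection. A
    synthetic-data generator with planted ground truth emulates a plant
    genome annotation project at desk scale so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    rtracklayer,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
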