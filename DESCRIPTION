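Package: ervregnet
Title: Endogenous Retrovirus Enhancer Co-Option Analysis for Germline and
    Naive Pluripotent Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a pipeline for characterising endogenous retrovirus
    (ERV) subfamilies that act as shared enhancers of primordial germ
    cell-like cells (PGCLCs) and naive pluripotent cells. Provides a
    cell-type-specificity score based on the sum of squared residuals
    against a declared expression model, genomic permutation and
    GREAT-style binomial enrichment statistics for transposable-element
    (TE) loci, Fisher gene-set enrichment with odds-ratio-ranked Jaccard
    redundancy pruning, a phylogeny-guided sliding-window procedure that
    dates ERV insertions from primate ortholog presence/absence tables,
    and a split-read caller for insertionally polymorphic loci. A
    synthetic-data module generates every input with known ground truth
    so all stages are testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
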