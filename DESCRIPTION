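Package: sigperm
Title: Gene-Signature Permutation Testing, Consensus Clustering and
    SAM-Ranked Enrichment for RNA-Seq Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether an a-priori gene signature separates
    sample groups in bulk RNA-seq data, and whether annotated pathways
    respond to a treatment.  Implements RPKM quantification with expression
    filters and upper-quartile normalization; a signature-restricted
    principal-component MANOVA test calibrated against random gene sets of
    equal size; Spearman-distance hierarchical clustering; Brunet-style
    consensus non-negative matrix factorization with a cophenetic-coefficient
    rank survey; Mann-Whitney differential expression with
    Benjamini-Hochberg correction; a SAM-ranked gene-set enrichment analysis
    with gene-label permutation, family-wise (maxT) correction and
    core-enrichment extraction; ordered-group trend and rank-correlation
    tests; and a synthetic count-data generator with planted structure for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    limma,
    fgsea,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
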