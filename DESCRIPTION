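Package: bgcmine
Title: Genome-Mining Analytics for Biosynthetic Gene Cluster Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for large-scale surveys of natural product
    biosynthetic gene clusters (BGCs) in bacterial isolate collections.
    Implements MinHash genome sketching with Mash-style distances for
    strain dereplication and putative-species delineation, cataloguing of
    antiSMASH-style BGC regions with chemical-class assignment and
    completeness statistics, region-to-reference similarity scoring from
    KnownClusterBlast/cblaster-style hit tables, gene cluster family (GCF)
    membership analytics over BiG-SLiCE distance assignments
    (core/putative/orphan strata, cross-dataset comparison), and
    chemical-space-guided molecular-family networking that joins genomic
    links with Morgan-fingerprint Tanimoto similarity between reference
    compounds. A synthetic-data module generates every input with planted
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    igraph,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
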