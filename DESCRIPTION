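Package: tagDGE
Title: Tag-Based Digital Gene Expression Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of SAGE-style digital gene expression (DGE) tag
    libraries against a de novo transcriptome reference. Builds a virtual
    NlaIII (CATG+17 nt) tag database from transcript sequences, filters raw
    tag libraries (adaptor/empty reads, 'N'-containing tags, low-complexity
    tags, copy-number-1 tags), maps tags with at most one mismatch while
    discarding multi-gene hits, quantifies per-gene expression in transcripts
    per million tags (TPM), and calls differential expression between two
    libraries with the Audic-Claverie exact test under Benjamini-Hochberg
    false discovery rate control. Includes library-evaluation summaries
    (tag-abundance distributions, sequencing saturation curves, between-
    library correlation) and a ground-truthed simulator of transcriptomes
    and tag libraries with incomplete digestion, sequencing error and
    contamination, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
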