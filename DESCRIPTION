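Package: chemomine
Title: Mining and Expression Analysis of Insect Chemosensory Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for identifying candidate odorant-binding
    protein (OBP) and chemosensory protein (CSP) transcripts in assembled
    insect transcriptomes. Candidates are mined by six-frame open reading
    frame discovery followed by PROSITE-style cysteine-spacing motif
    scanning with exhaustive anchor-assignment semantics, and classified
    into the general, classic-hemipteran and Plus-C OBP subfamilies or the
    CSP family. Downstream analyses cover pairwise amino-acid identity
    matrices from an affine-gap global aligner, p-distance neighbour-joining
    trees with bootstrap supports, RPKM abundance comparison between
    conditions, and qPCR relative quantification with standard-curve
    efficiency validation, multi-reference geometric-mean normalization and
    one-way ANOVA with LSD compact letter display. A synthetic-data module
    generates motif-planted proteins, transcript sets, count tables, Ct
    tables and alignments evolved on known trees so every stage is testable
    against planted truth.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    S4Vectors,
    ape,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
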