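Package: forcenet
Title: Force-Responsive ceRNA and Transcription-Factor Regulatory Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers competing endogenous RNA (ceRNA) networks and
    transcription-factor regulatory circuits that respond to mechanical
    force in bone cells. Provides differential expression under two force
    contrasts with BH-FDR and signed gene-set intersection, ingestion of
    literature-curated force-sensitive miRNA and pathway-lncRNA tables,
    evidence-filtered lncRNA-miRNA-mRNA triplet assembly with degree
    pruning and centrality consensus ranking, Pearson co-expression
    networks on TPM values, position-weight-matrix scanning of promoter
    sequences for TF binding sites, enumeration of closed
    TF-lncRNA-miRNA-TF feedback circuits, a generic hypergeometric
    over-representation test, and a synthetic-data generator that plants
    differentially expressed genes, ceRNA triplets, motif occurrences and
    feedback circuits with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
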