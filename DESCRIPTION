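Package: lmindex
Title: Lineage Maturation Index Scoring and Differentiation-Drug Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores the differentiation state of hematopoietic expression
    profiles with the Lineage Maturation Index (LMI), the scalar projection of
    a sample's log2 expression profile onto a reference lineage vector drawn
    from an immature endpoint (e.g. hematopoietic stem cells) to a mature
    endpoint (e.g. granulocytes), restricted to genes with at least a 4-fold
    expression change between the endpoints. Provides batch-controlled
    delta-LMI computation against vehicle (DMSO) controls, t-test based hit
    calling and ranking for drug-repurposing screens, gene-space harmonization
    and replicate averaging for expression matrices, synthetic lineage and
    screen generators with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
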