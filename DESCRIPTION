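Package: netpharm
Title: Network Pharmacology Inference for Multi-Herb Formulas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of the network-pharmacology inference
    pipeline used to study multi-herb formulas such as Xia Qi Decoction (XQD)
    against lung cancer: ADME screening of candidate ingredients on oral
    bioavailability (OB) and drug-likeness (DL) with per-herb threshold
    overrides, construction of typed herb-ingredient-target networks,
    degree/betweenness/closeness centrality with rule-based key-node
    selection, confidence-filtered protein-protein interaction (PPI)
    subnetworks with hub detection, hop-distance classification of disease
    genes into direct and indirect therapeutic targets, hypergeometric
    pathway over-representation, and a chi-square screen for immune-tissue
    specific expression. Ships curated example tables for the eight-herb XQD
    formula and seeded synthetic-data generators with planted ground truth so
    every pipeline stage is testable without database access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
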