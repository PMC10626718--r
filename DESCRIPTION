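Package: coexcons
Title: Comparative Coexpression Networks and Expression Conservation of Orthologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sign-aware Spearman coexpression networks around query
    genes from filtered FPKM expression matrices, rescores interactions with
    the mutual-rank statistic and a top-percentile reliability rule, pairs
    highly similar orthologs between two species by orthogroup-constrained
    reciprocal best BLAST hits, and quantifies the conservation of expression
    behaviour of ortholog pairs with an iterative weighted-correlation
    expression-conservation (EC) statistic. A seeded latent-factor simulator
    generates expression matrices, hit tables, orthogroup and domain tables
    with known ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
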