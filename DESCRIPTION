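Package: mitosyn
Title: Mito-Nuclear Association and Epistasis Analysis in Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assigns mitochondrial haplogroups (H, J, K, U) from five marker
    SNPs, tests case-control carriership association with Fisher's exact test
    and Woolf confidence intervals for the odds ratio, exhaustively mines
    haplogroup-by-nuclear-variant allelic combinations, and assesses epistasis
    between two carriership factors with the synergy factor and an exact
    conditional test of no three-way interaction in a 2x2x2 table. Includes a
    retrospective case-control cohort simulator and exact fixture
    reconstruction from aggregate carrier counts, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
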