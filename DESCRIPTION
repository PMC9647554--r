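Package: insomniaCEA
Title: Decision-Tree Cost-Effectiveness Model for Insomnia Pharmacotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-tree cost-effectiveness model comparing insomnia
    pharmacotherapies (lemborexant, suvorexant, zolpidem immediate release)
    and untreated insomnia from the Japanese healthcare payer perspective
    over a six-month horizon. Accrues quality-adjusted life years and direct
    medical costs through three adverse-event pathways (falls with a
    fracture/hospitalisation cascade, motor vehicle collisions, workplace
    accidents), classifies pairwise comparisons by dominance or incremental
    cost-effectiveness ratio, and quantifies parameter uncertainty with
    one-way (tornado) analyses, deterministic threshold search, and
    Monte-Carlo probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
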