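Package: regdissect
Title: Disentangling Direct and Indirect Effects of Global Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for separating regulation-specific (direct)
    from growth-rate-mediated (indirect) effects of global transcription factors
    using single- and double-deletion mutant expression panels. Quantifies
    epistatic cross talk between regulators from double-mutant additivity,
    classifies mutant targets against a growth-rate-matched chemostat reference
    and binding evidence, infers interacting-TF activities by enrichment rules
    and network component analysis with bootstrap confidence intervals, and
    screens high-confidence metabolite-TF interactions through a tiered Pearson
    correlation filter with pathway-impact and subsystem criteria. Ships a
    ground-truth synthetic data generator emulating an E. coli-like strain panel
    so every stage is testable by recovery of planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
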