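Package: ewsrepo
Title: Connectivity-Based Drug Repurposing and Preclinical Analysis for
    Ewing Sarcoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end computational drug-repurposing toolkit built
    around Ewing sarcoma. Constructs disease, fusion-silencing and
    chemoresistance gene-expression signatures; scores drug perturbation
    rank profiles against them with a bidirectional Kolmogorov-Smirnov
    connectivity statistic, permutation significance and FDR-gated top-K
    hit selection; normalizes 384-well high-throughput screens with
    Z-prime quality gating and counter-screen hit calling; fits
    median-effect dose-response curves and Chou-Talalay combination
    indices on 9x9 dose matrices; performs non-compartmental
    pharmacokinetic analysis of blood gold concentrations with
    auranofin-to-gold unit conversions; and compares survival arms with
    Kaplan-Meier curves and log-rank tests. A seeded synthetic-data
    generator with planted ground truth emulates every input so the whole
    pipeline is testable without external databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
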