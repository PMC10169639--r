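Package: demkin
Title: Serial In Vivo Demethylation Kinetics in Hypomethylating-Agent-Treated AML
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for serial (day 0 / day 8 / day 15) DNA
    methylation and expression array data from decitabine-treated AML
    patients. Implements paired empirical-Bayes moderated differential
    methylation on m-values with delta-beta/FDR calling, per-patient
    single-sample demethylation sets, a random-CpG-set resampling null for
    non-random common demethylation, cycle-to-cycle signature concordance,
    bystander T-cell contrasts, a responder 80/20 screen, genomic-context
    enrichment, and a gene-wise Spearman anti-correlation screen between
    promoter demethylation and transcript induction. Ships a synthetic
    cohort generator with ground truth so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
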