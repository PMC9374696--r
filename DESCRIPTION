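Package: cyclescan
Title: Circadian Cycling-Gene Detection for Short TPM Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects circadian cycling genes in short (six-point) bulk RNA-seq
    time courses using a best-fit-sinusoid maximum-correlation statistic with a
    Monte Carlo empirical p-value, as used for continuous-light transcriptome
    studies in cyanobacteria. Includes fold-change differential expression
    between culture conditions, Fisher exact term enrichment with a two-branch
    term-selection rule, phase-sorted heatmap and index-scatter reporting, and
    a seeded synthetic-data generator that emulates the two-condition,
    two-replicate, six-time-point study design so every stage of the pipeline
    can be validated against planted ground truth.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
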