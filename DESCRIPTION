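Package: aseglmm
Title: Differential Allele-Specific Expression with Negative Binomial
    Mixed Models and Pooled Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects differences in allelic imbalance between subject
    groups from RNA-seq allelic counts at heterozygous SNPs using a
    negative binomial generalized linear mixed model with a per-subject
    random intercept and an allele-by-group interaction test. Includes
    readers and testability filters for ASEReadCounter-style count
    tables, a counting and testing pipeline for pooled 3'UTR reporter
    assays (barcode demultiplexing, UMI deduplication, allele
    assignment, RNA-vs-DNA negative binomial tests), an ethanol
    dose-response model for allelic ratios, power simulation for
    allelic-imbalance designs, and a synthetic-data generator that
    emulates the statistical structure of all three experiments for
    validation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    pracma,
    Biostrings,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    MASS
Config/testthat/edition: 3
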