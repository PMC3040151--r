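Package: zdosage
Title: Dosage Compensation Analysis for ZZ/ZW Sex-Chromosome Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying sex-chromosome dosage compensation in
    female-heterogametic (ZZ/ZW) species from RNA-seq read counts and
    quantitative PCR copy-number assays. Implements RPKM quantification with
    orthology-based chromosome assignment and core gene-set filtering,
    GC-content bias estimation and removal, chromosome-wise male-to-female
    expression-ratio inference by no-intercept regression with Bonferroni
    confidence intervals, Z-to-autosome expression ratios per sex with
    bootstrap intervals, sex-bias classification and its relationship to
    expression level, cross-species correlation of sex-biased expression over
    one-to-one orthologues, delta-Ct relative quantification with gene-level
    Z-linkage calling, and a fully ground-truthed synthetic-data generator
    (negative-binomial counts, tunable compensation degree, GC-correlated
    bias, simulated qPCR plates) so the entire pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
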