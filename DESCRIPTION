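Package: oligoscape
Title: Cohort-Level Genomic Landscape Analysis for Anaplastic Oligodendroglioma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-level computations for anaplastic oligodendroglioma (AO)
    genomics: a binomial gene-set mutation-burden test against a uniform
    per-base cohort mutation rate, ploidy-relative allele-specific copy-number
    aberration and LOH classification with focal-event and arm-recurrence
    summaries, molecular-subtype assignment from IDH hotspot and 1p/19q
    co-deletion status with TERT promoter annotation, memo-sorted mutation
    landscape summaries, fusion-candidate read-support filtering against a
    normal-tissue blacklist, mutant-versus-wild-type expression contrasts with
    hypergeometric gene-set over-representation, exact binomial
    confidence intervals and 2x2 categorical tests, and a synthetic-cohort
    generator with exported ground truth so every stage is testable without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
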