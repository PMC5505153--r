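Package: itegs
Title: Integrated Gene-Set Tests of Joint Methylation and Expression Effects
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Variance-component score tests for the total effect of a gene
    set on a binary outcome, integrating CpG methylation, mRNA expression
    and their within-gene interactions. Implements per-gene kernel
    statistics under four disease-model specifications (M, G, MG, MGC),
    set-level pooling (iTEGS), and two omnibus procedures (iNOTE-chi and
    iNOTE-uni) calibrated by characteristic-function inversion, the
    Satterthwaite approximation, or resampling-based perturbation of the
    score statistics. Includes a simulator of correlated CpG blocks and
    downstream expression with case-control sampling for size and power
    studies, and a scanner for GMT gene-set collections.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
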