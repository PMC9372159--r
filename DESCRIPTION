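Package: clonehist
Title: Clonal Evolution and Histogenesis Analysis for Multi-Region Tumour Microbiopsies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-region laser-capture microbiopsy
    sequencing of germ cell tumours and similar cohorts: low-depth variant
    rescue with a panel-based beta-binomial site error model, Dirichlet-process
    clustering of cancer cell fractions, clone tree assembly and the
    trunk-proportion statistic, mutation-multiplicity timing of whole-genome
    duplication with a copy-number-adjusted pre-duplication burden,
    histology-versus-clone similarity permutation tests, chromosome-arm dosage
    expression permutation, and mutational-signature attribution by
    expectation-maximisation. A synthetic-cohort simulator with full ground
    truth exercises every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
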