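Package: neoscreen
Title: Variant Triage, Quality Monitoring and Benchmarking for Gene-Panel Newborn Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a gene-panel genomic newborn-screening
    workflow. Implements a variant interpretation decision tree for
    asymptomatic neonates (panel, depth/quality, population-frequency and
    knowledge-base classification filters followed by inheritance-aware
    zygosity resolution), IQR-fence derivation of sequencing quality-control
    thresholds with VIP-metric repeat semantics and Levey-Jennings
    longitudinal monitoring, and a region-restricted truth-set comparison
    engine reporting sensitivity, precision and pairwise concordance
    stratified by variant type. Ships a deterministic synthetic fixture
    generator (panels, knowledge bases, sample VCFs with planted scenarios,
    truth/test VCF pairs, QC metric histories) with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    vcfR,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
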