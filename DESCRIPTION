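Package: ccfdna
Title: Methylation-Based Quantification of Colon-Derived Cell-Free DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies colon-derived cell-free DNA (c-cfDNA) from targeted
    bisulfite amplicon sequencing using tissue-specific DNA methylation
    markers, and runs the downstream treatment-response statistics used in
    liquid-biopsy monitoring of neoadjuvant chemoradiation for rectal cancer.
    Reads are demultiplexed by barcode, aligned bisulfite-aware to amplicon
    references with a score threshold of -0.2 times the read length, CpGs are
    called as CG (methylated) or TG (unmethylated), and the fraction of fully
    unmethylated molecules per marker is converted to genome equivalents per
    ml of plasma. Includes seeded simulators for plasma read mixtures and
    longitudinal patient cohorts, plus Mann-Whitney, Fisher exact, ROC/AUC
    with DeLong confidence intervals, Kaplan-Meier/log-rank, and a
    baseline-to-week-2 c-cfDNA dynamics classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    jsonlite,
    pROC,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
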