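Package: qpcrstab
Title: Reference-Gene Stability Evaluation and Consensus Ranking for RT-qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evaluates candidate RT-qPCR reference genes from quantification-cycle
    (Cq) panels using five independent expression-stability algorithms (Brunner
    stability index, geNorm M values with pairwise variation, NormFinder variance
    decomposition, BestKeeper descriptive index, and the comparative delta-Ct
    method), merges the five rankings into a consensus ordering by Cross-Entropy
    Monte-Carlo minimisation of the mean Spearman footrule distance, estimates
    per-amplicon PCR efficiency from raw amplification curves by
    window-of-linearity regression, and performs efficiency-corrected relative
    quantification of a target gene against a chosen reference set. A synthetic
    study generator with known ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
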