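Package: miRpanel
Title: Serum miRNA Biomarker Panel Discovery via Correlation-Stratified
    Classification and Co-Target Synergy Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering serum miRNA biomarker
    panels from two-group expression microarrays: differential-miRNA
    screening (moderated or Welch t statistics with Benjamini-Hochberg
    false discovery rate control), Pearson correlation-stratified feature
    evaluation with a radial-basis-kernel support vector machine under
    stratified cross-validation scored by ROC/AUC, hypergeometric
    co-target synergy testing of miRNA pairs against pathway gene sets,
    construction of the miRNA-miRNA synergy network, overlapping module
    detection by the clique percolation method, and global network
    topology summaries.  A synthetic-data generator reproduces the
    two-group microarray structure the analysis assumes (planted
    differential miRNAs, latent-factor correlation blocks, missing
    values, planted co-target synergy pairs) so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    e1071,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
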