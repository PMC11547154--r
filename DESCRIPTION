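Package: lncmeth
Title: Hypermethylated lncRNA Gene Analysis for Epithelial Ovarian Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the epigenetic analysis of hypermethylated
    long non-coding RNA (lncRNA) genes in epithelial ovarian cancer: qPCR
    quantification (delta-delta-Ct relative expression and qMSP percent
    methylated reference), cohort group comparisons with Benjamini-Hochberg
    correction, methylation-expression correlation, co-expression partner
    screening, from-scratch Smith-Waterman complementarity alignment with
    miRNA seed-site classification, competing endogenous RNA (ceRNA) triplet
    assembly, EMT gene-set intersection reporting, Kaplan-Meier/log-rank/Cox
    survival analysis, and a k-of-n methylation marker panel with ROC/AUC.
    A seeded synthetic cohort generator emulates the statistical structure of
    a paired tumor/normal methylation study so that every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival,
    Biostrings,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
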