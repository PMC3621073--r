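Package: camtadep
Title: Classification of CAMTA1-Dependent Drought-Responsive Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing drought-responsive gene expression in a
    genotype-by-condition factorial microarray design. Calls differentially
    expressed genes with a permutation-based SAM-style d-statistic and
    fold-change/p-value gates, partitions wild-type drought-responsive genes
    into CAMTA1-dependent and -independent classes from the ratio of mutant
    to wild-type fold changes thresholded at the confidence interval of the
    attenuation distribution, scans promoter sequences for degenerate CAMTA
    recognition cis-elements (CGCG-box and CGTG/ABRE), cross-tabulates gene
    classes against stress, hormone and transcription-factor gene sets with
    Fisher enrichment and Benjamini-Yekutieli correction, and computes the
    accompanying physiology metrics (relative water content, survival rate,
    delta-delta-Ct fold change). A synthetic-data generator with recorded
    ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
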