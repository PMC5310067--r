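Package: methpanel
Title: Targeted Bisulfite Amplicon DNA Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for targeted bisulfite amplicon
    sequencing of DNA methylation panels: amplicon panel modelling with
    in-silico bisulfite conversion, demultiplexing and bisulfite-aware
    read assignment, per-CpG methylation calling with conversion-rate and
    binomial coverage filtering, logit-scale group statistics with
    data-driven test selection, per-CpG Fisher exact tests under
    Bonferroni family-wise error control, Spearman co-methylation
    networks, genotype-dosage association, and partial least squares
    discriminant classification. Includes a beta-binomial synthetic
    cohort generator emulating a two-tissue case/control study design so
    every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    car,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
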