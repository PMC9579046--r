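Package: radpep
Title: Radiation Immunopeptidomics and Proteogenomics Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for analysing radiation-induced
    changes in the cellular proteome and the MHC class I immunopeptidome.
    Builds paired normal/mutant neoantigen context databases from somatic
    variant calls and transcript models, performs label-free top-3 protein
    quantitation with scalar normalisation, maximum-likelihood imputation
    and empirical-Bayes moderated differential expression, applies
    target-decoy peptide-level FDR control, allele percent-rank binder
    classification, length/motif summaries and radiation-specific antigen
    discovery to immunopeptidome tables, cross-correlates proteome and
    immunopeptidome fold changes, analyses positional post-translational
    modification ratios, and computes absolute peptide copies per cell from
    parallel-reaction-monitoring standard curves. A seeded synthetic-data
    module generates every input with the statistical structure the
    analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
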