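Package: plasmakras
Title: Low-Abundance KRAS Mutation Detection in Plasma Cell-Free DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-sample negative-binomial error model for calling
    low-allelic-fraction KRAS substitutions from amplicon deep-sequencing
    read counts of plasma cell-free DNA. Sequencing errors at each position
    and base change are modelled by a robust negative-binomial regression of
    variant reads on depth (linear link, zero intercept); samples are called
    mutant when they are outliers from that regression at a Phred-scaled
    q-value above 30. Includes strand-bias statistics (RVSB), HGVS
    annotation of the two KRAS amplicons (codons 4-16 and 51-69, hg19),
    synthetic-data generators for the SW480 serial-dilution
    limit-of-detection experiment and pancreatic-cancer case-control
    cohorts, and the diagnostic evaluation stage: inclusion filters,
    per-subject mutation tallies, sensitivity/specificity with explicit
    denominators, the combined KRAS-or-CA19-9 test, stage trend,
    allelic-fraction comparisons and paired AUC tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    pROC,
    stats,
    utils
Suggests:
    Biostrings,
    VariantAnnotation,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
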