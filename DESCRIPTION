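Package: codaa
Title: Amino Acid Profiling, Protein Quality Scoring and Origin
    Discrimination for Dried Salted Cod
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the compositional and chemometric analysis of dried
    salted cod (Gadus morhua, Gadus macrocephalus) amino acid profiles:
    class and flavour partial sums, basis conversion between edible-portion
    and protein concentrations, FAO/WHO amino acid scores (AAS), limiting
    amino acid identification, the essential amino acid index (EAAI) with
    quality grading, one-way group comparisons with orthogonal contrasts and
    Tukey-adjusted pairwise tests, and forward stepwise canonical
    discriminant analysis with leave-one-out cross-validation for
    authenticating the geographic origin of samples. Includes packaged
    group-mean reference tables and a calibrated synthetic cohort generator
    emulating a three-origin, fifteen-samples-per-origin study design.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
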