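Package: surropep
Title: Design and Validation of Surrogate Internal-Standard Peptide Assays
    for Targeted Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying target-species proteins by LC-MS/MS using
    homologous peptides from a nonhuman matrix (for example bovine serum) as
    co-digested internal standards. Provides in-silico tryptic digestion,
    peptide monoisotopic mass, precursor and b/y fragment-ion m/z, and
    Kyte-Doolittle GRAVY calculation; homology-anchored pairing of
    species-specific target/surrogate peptides with selection and exclusion
    criteria; MRM transition enumeration with isobaric-conflict screening and
    quantifier/qualifier role assignment; calibration-curve fitting with
    LLOD/LLOQ estimation (3.3*sigma/S and 10*sigma/S), back-calculation,
    FDA/ICH-style calibrator and QC acceptance rules, and Wilcoxon comparison
    of internal-standard strategies; plus a seeded simulator of calibration
    plates and study samples with a shared digestion-efficiency factor for
    testing the co-digestion normalization claim end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
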