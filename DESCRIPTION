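Package: pahrisk
Title: Screening, Source Apportionment and Probabilistic Cancer Risk
    Assessment for Dietary PAH Residues
Version: 0.1.0
Authors@R:
    person("Analytics", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the residue-to-risk analysis of the 16 EPA priority
    polycyclic aromatic hydrocarbons (PAHs) in foodstuffs and herbal
    materials: contamination screening of censored (non-detect)
    concentration tables, diagnostic isomer-ratio source apportionment,
    benzo[a]pyrene toxic-equivalency (TEQ) scoring, incremental lifetime
    cancer risk (ILCR) computation with risk banding, and seeded Monte
    Carlo probabilistic risk assessment with best-fit distribution
    selection and contribution-to-variance sensitivity analysis.  Includes
    seeded synthetic-data generators emulating lognormal contamination
    with limit-of-detection censoring, so every pipeline stage is testable
    without raw laboratory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
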