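Package: pterisk
Title: Source-Oriented Probabilistic Health Risk Assessment of Potentially
    Toxic Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing contamination by potentially toxic elements
    (PTEs) across surface water, agricultural soil, and crops. Implements the
    single and Nemerow pollution indices and the Hakanson potential ecological
    risk index with their standard category schemes; a USEPA-style exposure
    model (ingestion, dermal contact, inhalation) yielding non-carcinogenic
    and carcinogenic risk indices for adults and children; Monte Carlo
    propagation of exposure-parameter uncertainty with exceedance
    probabilities and Spearman rank-correlation sensitivity analysis;
    principal-component source apportionment with Kaiser retention and
    varimax rotation; and source-to-risk attribution coupling the PCA
    contribution matrix to element-level risk shares. A synthetic-data
    generator produces concentration tables with known source structure and
    lognormal variability for end-to-end parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
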