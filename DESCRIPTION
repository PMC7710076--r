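Package: ednaqpcr
Title: Design and Validation Analytics for Species-Specific qPCR Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and validating hydrolysis-probe qPCR assays
    used to detect species from environmental DNA. Enumerates and ranks
    primer/probe candidates from a template under standard design criteria
    (product size, oligo size, nearest-neighbor melting temperature, GC
    content, 3' composition rules), screens assays against arbitrary sequence
    panels by mismatch-tolerant binding-site search, summarises binding-region
    conservation as position frequency matrices for sequence logos, and turns
    plate-level Cq data into standard curves, amplification efficiencies,
    limits of quantification, panel sensitivity/specificity, and
    back-calculated eDNA concentrations with confidence intervals. Seeded
    synthetic-data generators make the whole pipeline testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
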