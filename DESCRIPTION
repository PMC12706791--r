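Package: pyranoshift
Title: Structure Revision of Pyranoxanthones from 13C NMR Chemical Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing and revising published pyranoxanthone
    structures against their carbon-13 NMR data. Provides empirical
    carbon-class correction of DFT-calculated shifts (with Boltzmann
    conformer averaging), RMSD/maximum-deviation statistics and DP4
    candidate probabilities, a diagnostic-marker rule engine that
    classifies shift sets into pyranoxanthone subtypes, database-style
    dereplication with conflict and swapped-assignment diagnostics, a
    reproducible synthetic shift-table generator, and an end-to-end
    revision pipeline producing structured reports. All user-facing
    functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
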