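Package: paleosize
Title: Partitioning Community Mean Size Change in Dinoflagellate Cyst Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing changes in protist community mean size between
    two climate periods from paleoecological morphometric data. Computes
    community-weighted mean cyst diameters from individual measurements and
    assemblage counts, partitions the change between periods into intraspecific
    (within-species plasticity) and interspecific (species turnover)
    contributions, performs weighted and unweighted Welch two-sample tests,
    converts linear size changes to sphere-volume changes, and compares
    measured sizes against literature size ranges and midpoints. Includes a
    seeded synthetic-data generator emulating a six-species, two-period
    dinoflagellate cyst data set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
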