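Package: hostfeedr
Title: Host-Feeding Pattern Analysis of Mosquito Blood Meals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing host-feeding patterns of blood-fed
    mosquitoes from multi-site surveys: host-group tabulation and
    stratification (sampling period, land use), C-score null-model tests of
    host aggregation using fixed-equiprobable matrix randomization,
    contingency-table comparisons across periods and trapping methods,
    Jaccard/UPGMA host-feeding-group clustering, and a host-feeding based
    index of pathogen transmission risk to humans. Includes an in-silico
    cytochrome-b host identification stage (degenerate-primer search,
    amplicon extraction, best-identity assignment with a two-tier primer
    fallback) and a synthetic survey generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    vegan,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
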