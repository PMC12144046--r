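Package: prefrank
Title: Scaled Preference Rankings from Repeated Binary Choice Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns long-format binary preference data (forced choices or
    consumption quantities from two-option tests) into a scaled ranking of
    options via Bradley-Terry worth values, with two quality statistics for
    the derived ranking: the intransitivity ratio (share of cyclic option
    triples in per-subject tournaments) and the consensus error (scaled
    inter-subject disagreement over option pairs). Includes Monte-Carlo
    positioning of a new option from incomplete pairwise comparisons
    (uninformed and intransitivity-filtered informed simulation), a
    statistical cutoff rule for the number of randomization runs, and a
    synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
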