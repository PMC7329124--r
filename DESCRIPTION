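Package: tbicde
Title: Extract Traumatic Brain Injury Common Data Elements from Head CT
    Radiology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A lexicon-driven contextual-assertion pipeline that converts
    free-text non-contrast head CT radiology reports into a structured
    summary of 27 traumatic brain injury (TBI) common data elements, each
    carrying exactly one annotation (PRESENT, SUSPECTED, INDETERMINATE,
    ABSENT, NORMAL or ABNORMAL). Sentences are marked with lexical targets
    and contextual lexical modifiers (negations, hedges, affirmations),
    pruned by span containment, linked by directional scope, and reduced by
    character-distance pruning; report-level decision rules fill omitted
    targets with defaults, resolve duplicate mentions by majority vote with
    an ordered tie-break list, replace disallowed annotations by
    predetermined counterparts, and derive cross-target conclusions.
    Includes corpus preparation (section trimming, sentence splitting,
    n-gram TF-IDF cosine similarity, near-duplicate removal, similarity
    aware dataset partitioning), evaluation utilities (agreement classes,
    Cohen's kappa, two-case confusion counts, classification metrics,
    per-target error tables) and a seeded synthetic report generator with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
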