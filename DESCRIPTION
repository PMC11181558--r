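Package: synfilter
Title: Crowd-Voting Filter for Chemical Synonym-Structure Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resolves intra- and inter-depositor discrepancies in depositor
    provided chemical name to structure associations by crowd voting over a
    six-level ladder of chemical equivalence (exact structure, stereo,
    connectivity, and their parent-compound analogues), following the curation
    protocol used for large public compound databases. Includes parent
    compound selection for salts and mixtures, four voting strategies
    (single or multiple votes per depositor at 60% or 70% consensus),
    mapping of filtered synonyms to MeSH records with a 50% crowd vote,
    vocabulary exclusion and white/black-list overrides, a seeded synthetic
    submission generator with planted ground truth, and tabular reports of
    the filtering outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
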