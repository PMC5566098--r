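Package: forcensr
Title: Harmonisation, Quality Control and Dereplication of Planktonic
    Foraminifera Census Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to build a curated synthesis of planktonic foraminifera
    census counts from surface sediment samples in the style of the ForCenS
    database. Multiple overlapping source compilations are taxonomically
    harmonised against a master category scheme (synonym resolution,
    dataset-specific category merges, not-available marking), their metadata
    standardised and annotated with binary Error/Ocean/Database flags, their
    count data corrected, completed and renormalised, and quality filters
    applied. Duplicate records are then detected under conservative faunal
    similarity criteria combined with geodesic distance and sample-name edit
    distance thresholds, including repair of minutes-as-decimals coordinate
    mis-transformations, and merged with information-maximising precedence.
    A synthetic-corpus generator with a ground-truth ledger makes every
    pipeline stage testable, and readers/writers support the tab-delimited
    three-block layout with its not-available versus zero distinction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
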