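Package: hotspotr
Title: Fuzzy Hotspot Detection with Entropy-Based Reliability Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects circular spatial hotspots from point events (for example
    residences of diagnosed patients) with an extended fuzzy c-means
    clustering algorithm whose prototypes are circles (center plus radius)
    and whose cluster count is reduced at run time by merging mutually
    inclusive clusters. Each detected hotspot receives a reliability score
    in [0, 1] defined as one minus the De Luca-Termini fuzzy entropy of its
    membership degrees, and hotspots are classified into Low/Mean/High
    reliability classes either with fixed thresholds or with exact Jenks
    natural breaks. Includes a seeded generator of synthetic spatial event
    fields, longitude/latitude ingestion with UTM projection, GeoJSON export
    of hotspot circles, and ordinary least-squares tools for analysing how
    reliability depends on hotspot area and on the fluctuation of membership
    degrees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    geosphere,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
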