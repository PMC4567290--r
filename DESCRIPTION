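Package: afribee
Title: Identification of Africanized Honey Bees from Morphometrics and
    Mitochondrial Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring Africanization in Apis mellifera workers
    and colonies. Implements the standard four-measurement linear
    discriminant functions (forewing, hindwing, femur and tibia lengths)
    for individual workers and colony means, three in-silico
    mitochondrial assays (cytochrome b BglII restriction typing, the
    diagnostic C/T SNP in the COI DNA barcode, and COI-COII intergenic
    spacer lineage assignment by nearest reference), per-site mitotype
    summaries for hybrid-zone surveys, the accompanying statistics
    (goodness-of-fit chi-square against a reference proportion,
    pooled-variance t tests of discriminant scores by mitotype, a
    binomial site-heterogeneity test, and Wilson intervals for mitotype
    frequency), and a seeded synthetic-data generator that emulates a
    two-component African/European admixed population for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    MASS,
    readr,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
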