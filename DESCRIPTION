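Package: bamsieve
Title: Desk-Scale Distributed Filtering of BAM Cohorts and Read-Pair
    Inversion Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extended filtering of multi-individual BAM cohorts (SAM flag
    algebra, mapping quality, template-length range, sequence, CIGAR and
    optional-tag pattern predicates, region and cohort subsetting) with a
    one-task-per-file dispatch engine over pluggable data sources and sinks,
    a header-free self-contained "individual alignment format" for
    downstream aggregation, and a structural-variation scan that isolates
    inversion signatures from same-strand read pairs with inflated template
    length, applies alignment-purity and distinct-individual support
    filters, and renders per-chromosome population frequency matrices and
    population contrasts. Includes a seeded synthetic cohort generator that
    plants inversion and deletion signatures with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    jsonlite,
    optparse,
    yaml,
    parallel,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    png
SystemRequirements: samtools (>= 1.6)
Config/testthat/edition: 3
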