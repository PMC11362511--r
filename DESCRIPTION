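Package: surftime
Title: Time-Course Surfaceome Quantitation and Pattern Classification for
    Isobaric Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of TMT10plex time-course surfaceome
    labeling experiments. Converts MaxQuant-style reporter intensities into
    background-subtracted riBAQ-TMT protein abundances, imputes missing
    channel intensities by seeded chained-equations imputation, removes
    between-set batch effects by internal reference scaling (IRS) with a
    pseudo-reference, classifies five-point time courses by nearest
    theoretical model profile under the Bhattacharyya distance with
    simplified direction-pattern labels, and computes the enrichment,
    transition, prominence, differential-exposure and clustering statistics
    used to compare genotypes. Includes a synthetic-data generator with
    known ground truth emulating the two-genotype, three-replicate,
    five-time-point study design, plus small utilities for peroxidase
    activity assays and western-blot densitometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
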