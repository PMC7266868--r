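Package: droughtnet
Title: Cross-Variety Hormone Co-Expression Network Analysis for Long-Term
    Drought Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline from time-course expression matrices (FPKM
    scale) and hormone measurements to a cross-variety common regulatory
    network of hormone signaling under drought stress. Implements stage-wise
    differential expression calling (fold change plus Benjamini-Hochberg
    FDR), consensus Pearson/Spearman correlation networks per variety and
    condition, differential (control versus drought) edge classification,
    protein-family-level common-network construction across varieties,
    degree-based hub identification, and Duncan's multiple range test with
    compact letter displays. A synthetic-data module emulates the two-variety,
    two-condition, five-time-point study design with planted differentially
    expressed genes and a planted hub-centred correlation structure, so the
    full pipeline runs and is validated without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
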