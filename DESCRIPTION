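Package: rarecascade
Title: Rare-Variant Collapsing Burden Cascade for Case-Control Exome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A gene-discovery cascade for residual disease risk in
    case-control exome cohorts: site-level variant quality control,
    construction of five qualifying single-nucleotide-variant sets from
    deleteriousness predictor calls, a per-gene collapsing (carrier) burden
    test with a two-sided Fisher exact test and odds-ratio screen,
    gene-evidence mapping against lipid and cardiovascular databases, and
    carrier-versus-noncarrier phenotype regression with pathway-pattern
    filters for lipid, thrombosis and inflammation signatures. Ships a
    synthetic case-control exome cohort generator with planted risk genes
    so the full cascade is testable end to end without access-restricted
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
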