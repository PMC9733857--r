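Package: ecozoner
Title: Ecosystem-Service Importance Assessment and Zoning on Raster Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses the importance of ecosystem services on an aligned raster
    landscape and partitions it into protection tiers. Implements four per-cell
    service models (habitat quality under proximity-weighted threats, land-cover
    carbon stocks, Budyko-curve annual water yield, and USLE soil retention with
    EPIC erodibility), objective entropy weighting of the four services at the
    grid-cell scale, a weighted importance score, and four-tier Jenks
    natural-breaks zoning with per-tier area accounting. Ships a seeded
    synthetic-landscape generator emulating a mountainous, woodland-dominated
    study region so the full pipeline runs and is testable offline, plus a
    config-driven orchestrator with run manifests.
License: MIT
Encoding: UTF-8
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    EBImage,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    purrr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
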