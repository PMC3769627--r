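Package: divrich
Title: Clade Diversification Rates and Tests of Exceptional Species Richness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates clade-level net diversification rates from standing
    species richness and crown-group ages under a constant-rate pure-birth
    (Yule) model, and tests clades for exceptional species richness against
    95% confidence bounds of expected clade size under a background
    birth-death process with relative extinction, following the taxonomic
    likelihood framework of Magallon and Sanderson. Includes utilities for
    reading and validating ultrametric chronograms, a constant-rate
    birth-death chronogram simulator with optional incomplete taxon
    sampling used as an independent Monte-Carlo oracle, and a pipeline
    reproducing the New World Hypericum analysis from its published clade
    table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
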