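Package: trpindole
Title: Bioprospecting, Flux Analysis and Bioconversion Accounting for
    Tryptophanase-Based Indole Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-cell bioconversion of l-tryptophan to
    indole by bacterial tryptophanases (TNA, EC 4.1.99.1). Covers enzyme
    bioprospecting by global-alignment percent-identity clustering of protein
    families, constraint-based metabolic modelling (GPR-based model reduction,
    flux balance analysis, artificial-centering hit-and-run flux sampling, and
    decomposition of pyruvate-forming fluxes), Michaelis-Menten kinetics of the
    coupled TNA-LDH/NADH photometric assay, and stoichiometric process
    accounting (mol-percent conversion, space-time yield, two-phase in situ
    product recovery and mass-balance closure). Seeded synthetic-data
    generators provide sequence families with planted cluster structure, assay
    traces, fermentation time courses and two-phase equilibria for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
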