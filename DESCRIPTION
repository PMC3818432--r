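Package: iresscan
Title: Viral Internal Ribosome Entry Site Screening by RNA Structure Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans RNA sequences for candidate internal ribosome entry site
    (IRES) elements. Local secondary structures are predicted along the input
    by a windowed minimum-free-energy fold, aligned against reference IRES
    group templates (CrPV-, HCV-, EMCV- and PV-like) with an arc-annotated
    edit distance, scored with the ratio R = ALEN/DIST, screened for H-type
    pseudoknots, and classified per IRES group with linear-discriminant
    thresholds. Ships synthetic template and benchmark generators so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
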