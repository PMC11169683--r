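Package: bnhfacs
Title: Layered Bayesian Networks for HFACS-Coded Safety Incident Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of safety incident databases coded with the
    Human Factors Analysis and Classification System (HFACS). Builds the layered
    four-level Bayesian network implied by the HFACS hierarchy (organizational
    influences, unsafe supervision, preconditions for unsafe acts, unsafe acts),
    learns conditional probability tables from coded incident records with
    Dirichlet pseudo-count smoothing, performs exact inference by variable
    elimination (with a brute-force enumeration oracle), and computes the
    relative risk-change sensitivity statistic used to rank upper-level causes
    of unsafe acts. Includes a calibrated synthetic incident generator,
    parameter-recovery diagnostics, and an end-to-end reporting pipeline for
    radiotherapy incident-learning data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
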