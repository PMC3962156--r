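Package: provseq
Title: Provenance-Preserving Assembly of Bidirectional Sanger Reads and
    Base Mis-Call Impact Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembles forward/reverse Sanger read pairs into consensus
    sequences while recording, for every base, the chromatogram base-call
    position it derives from, so that any cell of a downstream multiple
    sequence alignment can be mapped back to the trace that produced it.
    Provides ambiguous-character and polymorphic-site detection reports
    anchored to chromatogram coordinates, a per-base sequencing-error
    injection model, coalescent and GTR+Gamma sequence simulators,
    site-frequency-spectrum summary statistics, and rejection approximate
    Bayesian computation for the population mutation rate, used to
    quantify how uncorrected base mis-calls bias phylogenetic and
    population-genetic inference.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    optparse,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
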