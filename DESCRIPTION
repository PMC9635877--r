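Package: rexloop
Title: Loop-Extrusion Simulation and Contact-Map Statistics for
    Condensin-Driven Chromosome Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for binned chromosome-conformation (Hi-C style)
    contact matrices and ChIP-style signal tracks, centered on the biology of
    C. elegans dosage compensation: iterative (ICE) matrix balancing,
    distance-decay P(s) profiles with log-derivative loop-size inference,
    A/B compartment eigenvectors and saddle strength (chromosome-wide and in
    local windows), diamond insulation scores with between-condition
    differencing, on-diagonal pileups at anchor sets such as rex sites, X/A
    ChIP-signal rescaling with consensus-peak and domain-level expression
    summaries, and a 1D lattice loop-extrusion simulator in which rex sites
    act as condensin DC loading sites and bidirectional probabilistic
    barriers for a one-sided extruder with a diffusible anchor. The
    simulator generates contact maps, occupancy tracks and expression tables
    so that every analytical claim can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
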