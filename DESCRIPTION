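Package: tidmapper
Title: Detection and Modeling of Transcription-Induced Domains in Bacterial Hi-C Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for sub-kilobase bacterial Hi-C contact maps:
    iterative (ICE) matrix balancing, low-coverage ("white line") bin masking,
    distance-decay estimation, detection of transcription-induced domains
    (TIDs, "bundles") by diagonal Gaussian-kernel convolution with second-envelope
    background removal, domain-border calling by directionality index (paired
    t-test) and multi-window relative insulation, gene-anchored contact pileups,
    and a two-variant probabilistic model linking RNA-polymerase occupancy to
    contact maps with a one-parameter (maximum occupancy) grid fit. Includes a
    seeded synthetic-data generator emulating circular bacterial genomes,
    power-law contact decay, operon layouts with log-normal expression, Poisson
    sequencing noise and plaid inter-unit enrichment, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
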