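Package: spurnet
Title: Detection of Potentially Spurious Edges in Delay-Weighted
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processing of directed interaction networks whose edges
    carry reconstructed interaction delays, as produced by bivariate
    effective-connectivity analyses (e.g. transfer entropy with delay
    reconstruction). A memoized dynamic program enumerates alternative
    paths whose summed delay matches a direct edge's delay within a
    user threshold; edges with such paths are tagged as potential
    cascade effects, and triangle motifs additionally yield simple
    common-drive tags. Includes pruning policies, directed weighted
    small-world, scale-free and random network generators, analytic
    path-count and estimation-cost calculators, brute-force oracles for
    verification, a hardware-independent benchmark harness, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
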