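Package: hammingnet
Title: Structure of Bit-String Similarity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and analysing similarity networks over sets of
    bit strings, where two strings are linked when their Hamming distance does
    not exceed a threshold G. Provides a neutral-evolution simulator that
    generates random bit-string populations, exact analytic results for the
    degree distribution, giant-component fraction, species richness and mean
    clustering coefficient of these networks, empirical structural metrics
    (components, clustering, degree assortativity, mean geodesic distance)
    with an Erdos-Renyi comparator, and seeded experiment drivers that
    regenerate the model's characteristic curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
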