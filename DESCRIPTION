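Package: cercalarray
Title: Morphogen-Based Patterning of the Cricket Cercal Filiform Hair Array
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the development of the filiform mechanosensory hair
    array on the cricket cercus as the greedy Monte Carlo minimisation of a
    two-morphogen cost function on a conical surface: a short-range
    inhibitor released at each hair socket sets inter-hair spacing, and a
    long-range signal from the two lineage restriction lines prescribes
    each hair's movement axis. Includes exact and stepwise geodesic
    distances on the cone frustum, spatial point-pattern assessment with
    Ripley's L function, movement-angle histograms in flattened and
    body-centric coordinates with circular peak counting, ventral/dorsal
    density ratios, plain-text hair-table input/output, and seeded fixture
    generators (homogeneous Poisson, clustered, von Mises mixtures) for
    validating the statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
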