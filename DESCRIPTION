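Package: dmcmcp
Title: Discrete Markov Chain Monte Carlo with People
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measure subjective category distributions over arbitrary discrete
    stimulus sets by running Markov chains whose acceptance step is a pairwise
    choice (human or simulated under the exponentiated Luce rule). Proposal
    graphs are built by maximum-weight b-matching on a pairwise similarity
    matrix (exact branch-and-bound on small instances, max-product message
    passing at scale); random-walk proposals (uniform-neighbor or
    geometric-walk, with a uniform jump mixture) preserve the symmetry the
    Barker acceptance function requires. Includes a session engine with
    practice and catch trials, chain linking across sessions and a
    binomial-tail exclusion rule; estimators and diagnostics for the
    stationary distribution (visit frequencies, cumulative feature averages,
    L1 histogram convergence curves, category choice proportions, top-k
    items); synthetic stimulus fixtures with known multimodal targets; and
    plain-text serialization for stimuli, similarity matrices, graphs,
    configurations and trial logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
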