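Package: gillesim
Title: Gillespie Simulation of Sequence Evolution with Indels Along
    Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-time Monte Carlo simulation of biological sequence
    evolution along a rooted phylogeny. Substitutions, insertions and
    deletions are integrated as concurrent Poisson processes via the
    exact Gillespie algorithm. Supports arbitrary-alphabet substitution
    models (K80, GTR, UNREST, GY94 codon model, empirical amino-acid
    matrices and fully general user matrices), among-site rate variation
    (+G, +I+G, user rules), multiple indel processes with per-site
    insertion and deletion tolerances ("field" models, including the
    rescaled fast field deletion process), node hooks for
    time-non-homogeneous evolution, and tracking of the true multiple
    alignment implied by the simulated indel history, for use as ground
    truth when benchmarking aligners.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    phangorn,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
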