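Package: hybnum
Title: Hybrid Numbers of Ploidy Profiles via Phylogenetic Networks with Beads
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes the hybrid number of a ploidy profile, i.e. the minimum
    number of polyploidization (reticulation) events a rooted binary
    phylogenetic network needs so that its root-to-leaf path counts equal the
    observed ploidy numbers. Provides a multigraph model of rooted
    phylogenetic networks that allows parallel arcs (beads), explicit
    realizations of simple profiles built from the binary representation and
    the prime factor decomposition of an integer, the simplification sequence
    of a profile, a traceback construction that realizes arbitrary profiles,
    an exact exhaustive attainment search for single-leaf networks, and a
    closed formula with certified upper and lower bounds when its hypothesis
    fails. Includes readers and writers for profile and arc-list tables,
    an extended Newick dialect with hybrid tags, DOT export, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
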