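Package: siterepeats
Title: Site-Repeat Aware Phylogenetic Likelihood Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the phylogenetic likelihood of DNA alignments on binary
    trees under GTR+Gamma models while detecting repeating site patterns
    ("site repeats") at every node of the tree. Conditional likelihood
    vectors are computed once per repeat class and stored in compressed
    form, which skips redundant work and reduces memory use. Repeat classes
    are found with a bounded lookup table and per-node integer identifiers,
    supporting both dynamic topologies (identifiers recomputed per call) and
    fixed topologies (identifiers cached at initialisation), as well as
    partial updates after local tree changes. Includes a reference
    (uncompressed) pruning implementation, brute-force oracles, and a
    sequence simulator so that all claims are testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
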