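Package: crocsize
Title: Scaffold-Constrained Parsimony and Phylogenetic Body-Size Estimation
    for Crocodyliforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for morphology-based phylogenetics of crocodyliforms and
    phylogenetic estimation of fossil body size. Reads TNT and NEXUS discrete
    character matrices with ordered (morphocline) characters, scores and
    searches trees under Fitch/Wagner (Sankoff) parsimony with a molecular
    scaffold backbone constraint, builds strict and reduced consensus trees,
    time-calibrates cladograms with the minimum-branch-length (mbl) method,
    fits head-width to total-length allometric regressions with Pagel's
    lambda phylogenetic signal, imputes total body length for fossil tips
    from head width under a Brownian-motion model by MCMC, and reconstructs
    ancestral body-size bins and osmoregulation states by parsimony.
    Includes generators for synthetic trees, Mk-type character matrices and
    allometric data so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
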