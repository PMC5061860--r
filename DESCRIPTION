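Package: netfold
Title: Folding and Unfolding of Phylogenetic Networks and MUL-Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the calculus relating multi-labelled trees (MUL-trees)
    and rooted phylogenetic networks: unfolding a network into the MUL-tree of
    its root paths, folding a MUL-tree back into a network by merging repeated
    subtrees, deciding whether a network is stable (folding its unfolding
    recovers the network), verifying folding maps and vertex partitions in the
    spirit of graph fibrations, testing whether a tree is displayed or weakly
    displayed by a network (the latter by a polynomial dynamic program with
    reconciliation-map witnesses), and a gadget-based reduction that turns any
    display instance into an equivalent one on a binary, compressed,
    tree-sibling network. Includes extended-Newick and JSON edge-list readers
    and writers, exact isomorphism tests built on canonical forms, and seeded
    generators for random trees, MUL-trees and networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
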