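Package: isorec
Title: Isometric Gene Tree Reconciliation with Exact Branch Lengths
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconciles a gene tree with a species tree under the isometric
    model, in which branch lengths of both trees must be respected exactly.
    Implements the rooted/rooted algorithm, the algorithm for an unrooted
    gene tree against a rooted species tree, a parametric algorithm that
    enumerates all root positions when both trees are unrooted, and a
    branch-length scaling variant for rooted trees. All arithmetic is exact
    (rational numbers), so equality tests in the algorithms are well posed.
    Includes the simple/inferable history formalism for classifying species
    tree nodes as speciations, duplications, losses and samples, and a
    seeded simulator of gene family evolution that produces reconciliation
    inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, optparse, stats, utils
Suggests: testthat (>= 3.0.0), ape, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
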