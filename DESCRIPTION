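Package: phylodraw
Title: Phylogenetic Tree Manipulation, Branch Selection, Layout and SVG
    Rendering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for working with rooted phylogenetic
    trees as application middleware: reading and writing Newick together
    with common annotation dialects (HyPhy-style {tag} branch markers and
    BEAST-style [&key=value] comments), minimal PhyloXML and NeXML
    readers, pre/post-order traversal with per-node computed metadata,
    ladderization, clade collapsing and hiding, multi-category branch
    selection with callback notification and annotated-Newick
    serialization, rectangular (phylogram/cladogram) and radial layout
    computation, tanglegram construction with exact dynamic-programming
    crossing minimization, and deterministic SVG rendering of trees and
    tanglegrams.  Includes a seeded Yule (pure-birth) tree simulator so
    the whole pipeline is testable without external data, and a
    command-line interface over the main pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    xml2
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
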