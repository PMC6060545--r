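# phylodraw

Rooted phylogenetic trees as *middleware*: a desk-scale R toolkit for
reading, annotating, laying out and drawing trees, built for workflows in
which a branch selection made in one place is consumed somewhere else —
e.g. marking *test* and *reference* branch sets for selection-pressure
analyses (RELAX-style test/reference splits), or comparing two topologies
of the same taxa as a tanglegram.

It is aimed at molecular evolution practitioners and tool builders who
need, in one coherent data model:

* **Newick I/O with annotation dialects** — plain Newick, HyPhy-style
  `{TAG}` branch markers, and BEAST-style `[&key=value]` comment blocks,
  with exact round-tripping of child order, labels, branch lengths, and
  tags; minimal read-only PhyloXML and NeXML support.
* **Traversal and manipulation abstractions** — `traverse_and_compute()`
  (pre/post-order visitors writing per-node payloads), `ladderize()`,
  subtree collapsing (a clade becomes a single leaf slot with a spline
  boundary sketch) and hiding.
* **Multi-category branch selection** — clades, root paths, individual
  branches, all-external/all-internal sets, and branches near a point in
  layout space; callbacks fire on every update; selections serialize to
  annotated Newick and parse back losslessly.
* **Layouts** — rectangular and radial, each as phylogram (x or radius
  proportional to cumulative branch length) or cladogram (all leaves at
  equal depth).
* **Tanglegrams with exact crossing minimization** — two trees, a
  (possibly many-to-many) leaf matching, and child-order optimization.
* **Deterministic SVG rendering** of trees and tanglegrams.
* A seeded **Yule (pure-birth) simulator** so everything above is
  testable without external data, and a command-line front-end.

## The core algorithm: tanglegram crossing minimization

With left leaves at ranks 1..n_L (depth-first under the current child
order) and right leaves likewise, two links (a, b) and (c, d) cross iff

    (rank(a) − rank(c)) · (rank(b) − rank(d)) < 0 .

Reordering a node's children never changes the topology, but it permutes
leaf ranks and hence crossings. For a fixed left tree, any two links with
distinct right leaves separate at exactly one node of the right tree
(their LCA), and whether they cross is decided solely by the order of that
node's child blocks together with the links' left-side ranks. Per-node
choices are therefore independent, and a single bottom-up pass choosing
the cheaper child order at each node (`minimize_crossings(tg, "right")`)
attains the global optimum over all 2^k flips (k free binary nodes);
multifurcations are handled by enumerating each node's child permutations
up to a degree cap. For `free_side = "both"` the left tree's orientation
space is enumerated with the right side solved by the same DP, which is
again exact on desk-scale instances. `brute_force_min_crossings()` is an
independent exhaustive oracle used throughout the test suite.

## Worked example

```r
library(phylodraw)

tree <- parse_newick("((human:0.011,chimp:0.013)hominini:0.019,gorilla:0.035);")
tree
#> <ptree> 5 nodes, 3 leaves

## mark the human+chimp clade as "test", gorilla as "reference"
sel <- selection_state(tree, categories = c("test", "reference"))
sel <- apply_selection(tree, sel, "clade",
                       anchor = mrca(tree, c("human", "chimp")),
                       category = "test")
sel <- apply_selection(tree, sel, "branch",
                       anchor = node_by_label(tree, "gorilla"),
                       category = "reference")
serialize_selection(tree, sel)
#> "((human{test}:0.011,chimp{test}:0.013)hominini{test}:0.019,gorilla{reference}:0.035);"
```

Each selected branch carries its category as a `{tag}`; the clade
selection covers human, chimp *and* the clade's own subtending branch (3
tagged branches), and parsing the string with the `hyphy_tags` dialect
recovers the exact assignment — this is the interchange surface consumed
by downstream hypothesis-testing tools.

```r
tg <- tanglegram(parse_newick("((A,B),C);"), parse_newick("((A,C),B);"))
count_crossings(tg)                        # 1  (the B and C links invert)
minimize_crossings(tg, "right")$crossings  # 1  (left fixed: 1 is optimal)
res <- minimize_crossings(tg, "both")
res$crossings                              # 0
write_newick(res$tg$left)                  # "(C,(A,B));"
write_newick(res$tg$right)                 # "((C,A),B);"
```

With the left tree fixed no right-side flip removes the crossing, but
freeing both sides finds the common leaf order C, A, B and unravels the
tanglegram completely. `render_tanglegram_svg(res$tg)` draws it; the link
lines in the SVG then have zero geometric intersections.

A shell front-end with the same pipelines (`stats`, `ladderize`,
`select`, `render`, `tanglegram`, `convert`) is installed at
`inst/cli/phylodraw`:

```sh
Rscript inst/cli/phylodraw select tree.nwk --mode clade \
    --anchor-contains human,chimp --category test
```

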