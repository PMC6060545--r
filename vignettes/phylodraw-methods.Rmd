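---
title: "phylodraw: data model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phylodraw: data model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodraw)
```

phylodraw treats a phylogeny as a piece of application middleware: the
same in-memory tree is read from one of several formats, annotated by a
selection mechanism, laid out, drawn, and serialized for a downstream
consumer. This vignette records the model, the conventions that were
genuinely open choices, and what the package's tests do and do not
establish.

## The tree model

A tree is a plain list of nodes indexed by contiguous integer ids, with a
`root` id. Each node stores its label, the length of its *subtending*
branch (`NA` when absent — absence is distinguished from zero and writers
omit absent lengths, so round-trips are faithful), an ordered `children`
vector, a `tags` set of branch categories, `collapsed`/`hidden` flags,
and two open key–value maps (`payload` for computed metadata, `metadata`
for `[&...]` comment blocks).

Child order is a first-class property: it does not affect the topology
(the clade set), but it completely determines leaf order in layouts and
hence tanglegram crossings, so every operation except `ladderize()` and
tanglegram optimization preserves it, and both readers and writers keep
the input order.

Branches are identified with their child node — every non-root node has
exactly one subtending branch and the root has none, so the root is never
selectable or taggable. Multifurcations are allowed everywhere; only the
crossing-minimization DP constrains node degree, via an explicit cap.

`hidden` and `collapsed` are independent: hiding removes a subtree from
traversal and layout entirely, while collapsing keeps the node as a
single leaf slot with a boundary sketch and leaves the topology intact.
Collapse may nest; layouts honor only the outermost collapsed node.

### Traversal

`traverse_and_compute()` visits every non-hidden node exactly once, in
pre- or post-order, passing the visitor the node and the current tree, so
a post-order visitor can read the payloads it already wrote on the
children (the classic use is a child-sum recurrence; the suite checks it
reproduces `count_leaves()` at every node). Visitors may modify payload,
tags or label; changes to `id`/`parent`/`children` raise
`"traversal-mutation"`, since silent topology edits mid-walk are almost
always bugs.

## Newick dialects

The grammar is standard Newick (quoted labels with doubled single quotes,
decimal or exponent-notation lengths, underscores kept verbatim), plus
two annotation dialects:

* `hyphy_tags`: a `{TAG}` block *immediately after a node's label and/or
  its `:length`* attaches `TAG` to that node's subtending branch. The
  writer emits the tag right after the label. The placement rule is a
  documented choice: published examples of such annotated strings show
  the output but not a grammar, so the package fixes one and guarantees
  `parse(write(t)) == t` for it.
* `beast_comments`: `[&key=value,...]` blocks are preserved as opaque
  string-valued metadata, never interpreted — the contents of these
  blocks vary across producers and any typing here would be guesswork.

Under the `plain` dialect both block forms are syntax errors unless
`strip_unknown_comments` is set, in which case they are discarded;
stripping an annotated string and parsing it plain yields the same
topology as the annotating dialect (tested).

Branch lengths are written with a fixed number of digits after the
decimal point (trailing zeros trimmed), so "round-trip to precision"
means an *absolute* error below 10^-precision, not a relative one.

PhyloXML and NeXML support is read-only and minimal — clade nesting,
names and branch lengths for PhyloXML (attribute or element form); the
node/edge/otu records for NeXML with structural validation
(`"not-a-tree"` on multiple roots, duplicate parents, cycles or
disconnection). Writing these formats, and Nexus altogether, is out of
scope.

## Selection semantics

A selection state maps branches to sets of named categories. The
mechanisms mirror what an interactive tree viewer offers, made precise:

* *clade* selection includes the clade's own subtending branch, so a
  clade of k nodes selects k branches — this matches the test/reference
  workflow where an entire test clade, including its stem, is tagged;
* *path to root* takes every branch from the anchor up to the root;
* *near a point* is formalized as Euclidean distance from the query point
  to the **drawn branch segment** (parent-to-child in Cartesian layout
  coordinates) being within the radius. Distance to the segment, rather
  than to a single representative midpoint, was chosen because it makes a
  query at a node's own coordinates always hit that node's branch
  (distance 0), which is what a user pointing at a leaf expects.

Callbacks registered on the state run in registration order, exactly once
per applied update, receiving the tree and the post-update state — this
is the hook by which other application components react to selections.

Serialization to annotated Newick requires one tag per branch; a branch
in several categories is resolved by an explicit priority order or fails
with `"ambiguous-tag"`. The suite round-trips randomized selections
through the string form and back.

## Layout conventions

Fixed, documented conventions (none are configurable):

* Rectangular: x grows root→leaves, y grows downward; visible leaf slots
  get y = 0, s, 2s, … in depth-first order (`leaf_spacing` s, default 1).
* Radial: angles in radians, counter-clockwise from the positive x-axis;
  n leaf slots at 2πk/n.
* An internal node sits at the arithmetic mean of its visible children's
  y (or angle) — the mean of *all* children, not just the extremes, so a
  heavy multifurcation pulls its parent toward the bulk of its leaves.
* Phylogram: x (or radius) is cumulative branch length from the root,
  rescaled so the deepest visible node sits at `width` (`radius`). A
  missing length counts as 0 with a single warning — an error here would
  make mixed-source trees unusable, and silently inventing a length
  would be worse.
* Cladogram: internal positions are edge-count depth over maximum depth;
  every leaf slot is pushed to full width/radius (leaf-position variance
  0, tested).
* Edge paths are axis-parallel elbows (rectangular) or an arc at the
  parent radius plus a radial segment (radial).

A collapsed node occupies exactly one leaf slot. Its boundary sketch
(`collapsed_boundary()`) is computed in *full-layout* coordinates — the
same layout parameters with all collapse flags cleared — as a closed
centripetal Catmull-Rom spline through the clade root's attachment point
and the subtree's leaf positions in envelope order. Catmull-Rom was
chosen over an interpolating convex hull because it passes exactly
through its control points, which yields the containment guarantee the
tests assert (every subtree leaf position lies on the polygon) without
depending on the curve's overshoot behavior; the knot parameterization is
centripetal (exponent 1/2, with a 1e-12 guard for coincident points) to
avoid cusps. In the collapsed layout itself, the `LayoutResult` carries a
small triangular wedge spanning the slot as the drawing glyph; the spline
polygon lives in the expanded coordinate frame where the leaf positions
it must contain are defined.

## Tanglegram crossing minimization

Links cross iff their endpoint ranks invert:
`(rank_L(a) − rank_L(c)) · (rank_R(b) − rank_R(d)) < 0`; links sharing an
endpoint never cross, so many-to-many matchings are well defined.

With the left side fixed, any two links with distinct right leaves
separate at exactly one right-tree node (their LCA), and their crossing
status depends only on that node's child-block order and the links'
left-side ranks. The per-node decisions are therefore independent, and a
bottom-up pass that, at each node, counts pairwise inter-block rank
inversions for every child permutation and keeps the cheapest one is
globally exact — for binary nodes this is the classical 2^k flip space,
and enumerating permutations per node extends it to multifurcations up to
`degree_cap` (default 8; beyond it the cost of the factorial enumeration
is no longer desk-scale and the call fails explicitly rather than
silently approximating).

Ties between child orders are broken toward the input orientation, so
optimization is stable: an already-optimal tanglegram is returned
unchanged.

For `free_side = "both"` the per-node independence argument no longer
applies across trees (left choices change the ranks the right DP
minimizes against). Alternating one-sided passes to a fixed point was
considered and rejected as the default: it can stall in a local optimum —
on the 3-leaf instance `((A,B),C)` vs `((A,C),B)` it stops at 1 crossing
although the true two-sided optimum is 0 (common leaf order C, A, B).
Instead the left tree's whole orientation space is enumerated with the
right side solved exactly by the DP for each assignment, which is
globally exact; the enumeration is capped (`max_enumeration`, default
65536 assignments ≈ 16 free binary left nodes), beyond which the solver
falls back to the alternating heuristic and says so via a message. Both
`minimize_crossings()` modes are checked against
`brute_force_min_crossings()`, an independent exhaustive-enumeration
oracle, on hundreds of random instances.

## Rendering

SVG output is a pure function of its inputs: fixed element order, fixed
`%.4f` coordinate formatting, no timestamps or generated ids, so two
renders of the same inputs are byte-identical (tested). Element counts
are exact functions of the model — one `<path>` per visible non-root
branch, one `<polygon>` per outermost collapsed clade, one
`<line class="link">` per matching pair. Styling is emitted as explicit
attributes plus class names, and categorized branches also carry a
`data-category` attribute, so downstream tooling (and the test suite) can
read selections back out of the image. Tanglegrams are drawn as two
mirrored cladograms so matched leaves face each other; geometric link
intersections in the SVG then equal the combinatorial crossing count.

## The generators, and what the tests do not show

`generate_yule_tree()` is a pure-birth simulator: starting from two
lineages, a uniformly chosen extant lineage splits at each event, and
exponential waiting times (rate `rate · k` for k lineages, default rate
1) accrue on every extant pendant branch — so trees are binary with
strictly positive lengths and `2n − 1` nodes. `generate_tangled_pair()`
derives the right tree from the left by seeded leaf-label swaps and
child-order scrambling, so the expected minimized crossing count is 0
exactly when no swaps are applied. All generation is seed-deterministic
and restores the caller's RNG state.

These generators exercise parsing, layout and optimization correctness,
which is topology- and length-agnostic; they do **not** emulate
coalescent effects, extinction, rate heterogeneity, polytomies, or
real-world label conventions. Passing tests therefore establish the
*algorithms'* contracts, not any biological realism of the fixtures.
Problem sizes used by the suite and by `scripts/acceptance.R` — 200
round-trip trees of 4–64 leaves, 200 tanglegram instances of 4–8 leaves
(where the brute-force oracle is exact and cheap), corpora of 20–40 trees
for layout and ladderize properties — were chosen so that every property
is exercised across a meaningful size range while the whole suite stays
interactive.

## Known limitations

* PhyloXML/NeXML are read-only and minimal; Nexus is unsupported.
* `free_side = "both"` beyond the enumeration cap is heuristic.
* Phylograms treat missing branch lengths as 0 (with a warning), which
  compresses those branches to their parent's depth.
* Rendering does no label-collision avoidance or font metrics; labels
  can overlap on dense trees.
* Rerooting and other structural edits are out of scope; the model is a
  rooted tree throughout.
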