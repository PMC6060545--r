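test_that("rectangular phylogram places the worked 2-leaf example", {
  lay <- layout_rectangular(parse_newick("(A:1,B:1);"),
                            "phylogram", leaf_spacing = 1, width = 1)
  expect_equal(unname(lay$coordinates[2, ]), c(1, 0))  # A
  expect_equal(unname(lay$coordinates[3, ]), c(1, 1))  # B
  expect_equal(unname(lay$coordinates[1, ]), c(0, 0.5))
})

test_that("cladogram pushes every leaf to full width", {
  t <- parse_newick("((A,B),C);")
  lay <- layout_rectangular(t, "cladogram", width = 1)
  xs <- lay$coordinates[leaf_ids(t), 1]
  expect_equal(unname(xs), c(1, 1, 1))
  expect_equal(stats::var(xs), 0)
  expect_equal(unname(lay$coordinates[t$root, 1]), 0)
})

test_that("rectangular invariants hold on a random corpus", {
  for (t in yule_corpus(6, 4, 30)) {
    lay <- layout_rectangular(t, "phylogram")
    lv <- leaf_ids(t)
    expect_false(anyDuplicated(lay$coordinates[lv, 2]) > 0)
    for (id in seq_len(n_nodes(t))) {
      ch <- t$nodes[[id]]$children
      if (length(ch) > 0) {
        y <- lay$coordinates[id, 2]
        expect_gte(y, min(lay$coordinates[ch, 2]))
        expect_lte(y, max(lay$coordinates[ch, 2]))
      }
      p <- t$nodes[[id]]$parent
      if (!is.na(p))  # x non-decreasing root-to-leaf
        expect_gte(lay$coordinates[id, 1], lay$coordinates[p, 1])
    }
  }
})

test_that("radial layout spaces leaves uniformly", {
  t <- parse_newick("((A,B),(C,D));")
  lay <- layout_radial(t, "cladogram")
  angles <- sort(lay$coordinates[leaf_ids(t), 2])
  expect_equal(angles, c(0, pi / 2, pi, 3 * pi / 2))
  # root angle = mean of its two children's angles
  ch <- t$nodes[[t$root]]$children
  expect_equal(unname(lay$coordinates[t$root, 2]),
               mean(lay$coordinates[ch, 2]))
  # 2-leaf phylogram: equal lengths put both leaves at the full radius
  two <- layout_radial(parse_newick("(A:1,B:1);"), "phylogram", radius = 1)
  expect_equal(unname(two$coordinates[2:3, 1]), c(1, 1))
})

test_that("radial leaf-angle gaps sum to a full turn", {
  for (t in yule_corpus(5, 4, 20)) {
    lay <- layout_radial(t, "cladogram")
    a <- sort(lay$coordinates[leaf_ids(t), 2])
    expect_true(all(a >= 0 & a < 2 * pi))
    gaps <- c(diff(a), 2 * pi - (a[length(a)] - a[1]))
    expect_equal(sum(gaps), 2 * pi)
    rl <- lay$coordinates[leaf_ids(t), 1]
    expect_equal(stats::var(rl), 0)  # cladogram: all leaves at full radius
  }
})

test_that("ladderizing permutes leaf rows but preserves count and extents", {
  t <- generate_yule_tree(16, 21)
  l0 <- layout_rectangular(t, "phylogram")
  l1 <- layout_rectangular(ladderize(t, "ascending"), "phylogram")
  lv <- leaf_ids(t)
  expect_setequal(l0$coordinates[lv, 2], l1$coordinates[lv, 2])
  expect_equal(l0$extents, l1$extents)
  expect_length(l1$leaf_order, 16)
})

test_that("a collapsed clade occupies exactly one leaf slot", {
  t <- set_collapsed(parse_newick("((A,B),C);"), 2, TRUE)
  lay <- layout_rectangular(t, "cladogram")
  expect_length(lay$leaf_order, 2)  # collapsed slot + C
  expect_identical(lay$leaf_order[1], 2L)
  # descendants of the collapsed node are not laid out
  expect_true(all(is.na(lay$coordinates[c(3, 4), 1])))
  expect_length(lay$collapsed_boundaries, 1)
  # hidden removes the subtree without a placeholder
  h <- set_hidden(parse_newick("((A,B),C);"), 2, TRUE)
  expect_length(layout_rectangular(h, "cladogram")$leaf_order, 1)
})

test_that("nested collapse honors only the outermost node", {
  t <- parse_newick("(((A,B)in,C)out,D);")
  t <- set_collapsed(t, node_by_label(t, "in"), TRUE)
  t <- set_collapsed(t, node_by_label(t, "out"), TRUE)
  lay <- layout_rectangular(t, "cladogram")
  expect_identical(names(lay$collapsed_boundaries),
                   as.character(node_by_label(t, "out")))
  expect_length(lay$leaf_order, 2)  # 'out' slot + D
})

test_that("degenerate layout parameters are rejected", {
  t <- parse_newick("(A:1,B:1);")
  expect_error(layout_rectangular(t, width = 0), "positive")
  expect_error(layout_rectangular(t, leaf_spacing = -1), "positive")
  expect_error(layout_radial(t, radius = 0), "positive")
  expect_warning(layout_rectangular(parse_newick("(A,B);"), "phylogram"),
                 "missing branch length")
})

test_that("collapsed boundary interpolates the attachment and leaf points", {
  t <- set_collapsed(parse_newick("((A:1,B:2)N:1,C:3);"), 2, TRUE)
  lay <- layout_rectangular(t)
  poly <- collapsed_boundary(t, lay, 2, samples = 10)
  expanded <- parse_newick("((A:1,B:2)N:1,C:3);")
  full <- layout_rectangular(expanded)
  on_poly <- function(pt) {
    min(sqrt((poly[, 1] - pt[1])^2 + (poly[, 2] - pt[2])^2)) < 1e-9
  }
  for (lab in c("A", "B"))
    expect_true(on_poly(full$coordinates[node_by_label(expanded, lab), ]))
  expect_true(on_poly(full$coordinates[2, ]))  # attachment point
  expect_error(collapsed_boundary(t, lay, 5, 10), "not collapsed")
})

test_that("boundary contains all leaf positions of a random collapsed clade", {
  t <- generate_yule_tree(10, 77)
  internal <- setdiff(which(vapply(t$nodes, function(nd)
    length(nd$children) > 0, logical(1))), t$root)
  sizes <- vapply(internal, function(i) count_leaves(t, i), integer(1))
  anchor <- internal[which.max(sizes)]
  tc <- set_collapsed(t, anchor, TRUE)
  lay <- layout_rectangular(tc)
  poly <- collapsed_boundary(tc, lay, anchor, samples = 25)
  full <- layout_rectangular(t)
  lv <- intersect(subtree_ids(t, anchor), leaf_ids(t))
  for (id in lv) {
    pt <- full$coordinates[id, ]
    expect_lt(min(sqrt((poly[, 1] - pt[1])^2 + (poly[, 2] - pt[2])^2)),
              1e-9)  # spline interpolates every leaf position
  }
  # refining the spline does not shrink the sketched region much
  a3 <- polygon_area(collapsed_boundary(tc, lay, anchor, samples = 3))
  a50 <- polygon_area(collapsed_boundary(tc, lay, anchor, samples = 50))
  hull_pts <- rbind(full$coordinates[lv, , drop = FALSE],
                    full$coordinates[anchor, ])
  hull <- hull_pts[grDevices::chull(hull_pts), ]
  expect_gte(a50, a3 - 0.05 * polygon_area(hull))
})
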