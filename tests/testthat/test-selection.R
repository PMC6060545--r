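test_that("each selection mechanism selects the specified branch set", {
  t <- parse_newick("((A,B)N,C);")
  s <- selection_state(t)
  n_id <- node_by_label(t, "N")

  s1 <- apply_selection(t, s, "clade", anchor = n_id, category = "test")
  sel <- selected_branches(s1, "test")
  expect_length(sel, 3)  # A, B and the (A,B) branch itself
  expect_setequal(sel, c(n_id, node_by_label(t, "A"), node_by_label(t, "B")))

  s2 <- apply_selection(t, s, "path_to_root",
                        anchor = node_by_label(t, "A"), category = "test")
  expect_setequal(selected_branches(s2, "test"),
                  c(node_by_label(t, "A"), n_id))

  s3 <- apply_selection(t, s, "all_external", category = "test")
  expect_setequal(selected_branches(s3, "test"), leaf_ids(t))

  s4 <- apply_selection(t, s, "all_internal", category = "test")
  expect_identical(selected_branches(s4, "test"), n_id)

  s5 <- apply_selection(t, s, "branch", anchor = node_by_label(t, "C"),
                        category = "test")
  expect_identical(selected_branches(s5, "test"), node_by_label(t, "C"))

  big <- generate_yule_tree(10, 3)
  sb <- apply_selection(big, selection_state(big), "all_external",
                        category = "test")
  expect_length(selected_branches(sb, "test"), 10)
})

test_that("clade selection size equals subtree node count on random trees", {
  for (seed in 1:5) {
    t <- generate_yule_tree(12, seed)
    internal <- setdiff(which(vapply(t$nodes, function(nd)
      length(nd$children) > 0, logical(1))), t$root)
    anchor <- internal[1 + seed %% length(internal)]
    s <- apply_selection(t, selection_state(t), "clade", anchor = anchor,
                         category = "test")
    expect_length(selected_branches(s, "test"),
                  length(subtree_ids(t, anchor)))
  }
})

test_that("near_point selection needs a layout and respects the radius", {
  t <- parse_newick("(A:1,B:1);")
  s <- selection_state(t)
  expect_error(apply_selection(t, s, "near_point",
                               anchor = list(point = c(1, 0), radius = 0.01),
                               category = "test"),
               "layout")
  lay <- layout_rectangular(t)
  a_id <- node_by_label(t, "A")
  s1 <- apply_selection(t, s, "near_point",
                        anchor = list(point = lay$coordinates[a_id, ],
                                      radius = 1e-9),
                        category = "test", layout = lay)
  expect_identical(selected_branches(s1, "test"), a_id)
  # a huge radius catches every branch
  s2 <- apply_selection(t, s, "near_point",
                        anchor = list(point = c(0.5, 0.5), radius = 100),
                        category = "test", layout = lay)
  expect_setequal(selected_branches(s2, "test"), c(2L, 3L))
})

test_that("callbacks fire once per update, in registration order", {
  t <- parse_newick("((A,B),(C,D));")
  log <- new.env(); log$calls <- character(0); log$last_n <- NA
  s <- selection_state(t)
  s <- register_callback(s, function(tree, state) {
    log$calls <- c(log$calls, "first")
    log$last_n <- length(selected_branches(state))
  })
  s <- register_callback(s, function(tree, state) {
    log$calls <- c(log$calls, "second")
  })
  s <- apply_selection(t, s, "all_external", category = "test")
  s <- apply_selection(t, s, "branch", anchor = 2, category = "test")
  s <- apply_selection(t, s, "branch", anchor = 2, category = "test",
                       action = "remove")
  expect_identical(log$calls, rep(c("first", "second"), 3))
  expect_identical(log$last_n, 4L)  # after removal, the 4 leaf branches
})

test_that("toggle twice is the identity; unknown categories error", {
  t <- parse_newick("((A,B),C);")
  s0 <- apply_selection(t, selection_state(t), "clade", anchor = 2,
                        category = "test")
  s1 <- apply_selection(t, s0, "all_external", category = "reference",
                        action = "toggle")
  s2 <- apply_selection(t, s1, "all_external", category = "reference",
                        action = "toggle")
  expect_identical(s2$assignment[order(names(s2$assignment))],
                   s0$assignment[order(names(s0$assignment))])
  expect_error(apply_selection(t, s0, "branch", anchor = 2,
                               category = "nope"), "unknown category")
})

test_that("test/reference split serializes to the annotated form", {
  t <- parse_newick("((A,B),C);")
  s <- selection_state(t)
  s <- apply_selection(t, s, "clade", anchor = 2, category = "test")
  s <- apply_selection(t, s, "branch", anchor = node_by_label(t, "C"),
                       category = "reference")
  out <- serialize_selection(t, s)
  expect_identical(out, "((A{test},B{test}){test},C{reference});")
  back <- selection_from_tags(parse_newick(out, "hyphy_tags"))
  expect_setequal(selected_branches(back, "test"),
                  selected_branches(s, "test"))
  expect_setequal(selected_branches(back, "reference"),
                  selected_branches(s, "reference"))
})

test_that("empty selections serialize to plain Newick", {
  t <- parse_newick("((A,B),C);")
  expect_identical(serialize_selection(t, selection_state(t)),
                   "((A,B),C);")
})

test_that("multi-category branches need a priority order", {
  t <- parse_newick("(A,B);")
  s <- selection_state(t)
  s <- apply_selection(t, s, "branch", anchor = 2, category = "test")
  s <- apply_selection(t, s, "branch", anchor = 2, category = "reference")
  expect_error(serialize_selection(t, s), "ambiguous-tag")
  out <- serialize_selection(t, s,
                             category_order = c("test", "reference"))
  expect_match(out, "A\\{test\\}")
})

test_that("random single-category selections round-trip through Newick", {
  for (seed in 1:10) {
    t <- generate_yule_tree(4 + seed %% 10, 500 + seed)
    sel_ids <- setdiff(seq_len(n_nodes(t)), t$root)
    keep <- sel_ids[seq_along(sel_ids) %% 3 == seed %% 3]
    s <- selection_state(t)
    for (id in keep)
      s <- apply_selection(t, s, "branch", anchor = id, category = "test")
    back <- selection_from_tags(
      parse_newick(serialize_selection(t, s), "hyphy_tags"))
    expect_setequal(selected_branches(back, "test"),
                    selected_branches(s, "test"))
  }
})
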