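test_that("traversal visits every node once in the requested order", {
  t <- parse_newick("((A,B),(C,D));")
  visited <- character(0)
  lab <- function(tree, id) {
    l <- tree$nodes[[id]]$label
    if (nzchar(l)) l else paste0("#", id)
  }
  traverse_and_compute(t, "preorder", function(node, tree) {
    visited <<- c(visited, lab(tree, node$id)); NULL
  })
  expect_length(visited, 7)          # binary 4-leaf tree has 7 nodes
  expect_identical(visited[1], "#1") # parent before children
  expect_lt(match("#2", visited), match("A", visited))

  visited <- character(0)
  traverse_and_compute(t, "postorder", function(node, tree) {
    visited <<- c(visited, lab(tree, node$id)); NULL
  })
  expect_length(visited, 7)
  expect_identical(visited[7], "#1") # parent after children
  expect_lt(match("A", visited), match("#2", visited))
})

test_that("postorder child-sum visitor reproduces count_leaves everywhere", {
  for (t in yule_corpus(5, 4, 24)) {
    t <- traverse_and_compute(t, "postorder", function(node, tree) {
      node$payload$n <- if (length(node$children) == 0) 1L else
        sum(vapply(node$children,
                   function(c) tree$nodes[[c]]$payload$n, integer(1)))
      node
    })
    for (id in seq_len(n_nodes(t))) {
      expect_identical(t$nodes[[id]]$payload$n, count_leaves(t, id))
      expect_identical(count_leaves(t, id), leaf_count_oracle(t, id))
    }
  }
})

test_that("preorder depth assignment follows the definition", {
  t <- parse_newick("((A,B),C);")
  t <- traverse_and_compute(t, "preorder", function(node, tree) {
    node$payload$depth <- if (is.na(node$parent)) 0L else
      tree$nodes[[node$parent]]$payload$depth + 1L
    node
  })
  expect_identical(t$nodes[[node_by_label(t, "A")]]$payload$depth, 2L)
  expect_identical(t$nodes[[node_by_label(t, "C")]]$payload$depth, 1L)
  expect_identical(t$nodes[[t$root]]$payload$depth, 0L)
})

test_that("topology mutation during traversal is detected", {
  t <- parse_newick("((A,B),C);")
  expect_error(
    traverse_and_compute(t, "preorder", function(node, tree) {
      node$children <- rev(node$children); node
    }),
    "traversal-mutation")
})

test_that("hidden subtrees are skipped by traversal; collapsed are not", {
  t <- parse_newick("((A,B)N,C);")
  t <- set_hidden(t, node_by_label(t, "N"), TRUE)
  seen <- integer(0)
  traverse_and_compute(t, "postorder", function(node, tree) {
    seen <<- c(seen, node$id); NULL
  })
  expect_length(seen, 2)  # root and C only
  t <- set_hidden(t, node_by_label(t, "N"), FALSE)
  t <- set_collapsed(t, node_by_label(t, "N"), TRUE)
  seen <- integer(0)
  traverse_and_compute(t, "postorder", function(node, tree) {
    seen <<- c(seen, node$id); NULL
  })
  expect_length(seen, 5)
})

test_that("ladderize sorts children by subtree size and preserves clades", {
  t <- parse_newick("((A,B,C)X,D)R;")
  asc <- ladderize(t, "ascending")
  first <- asc$nodes[[asc$root]]$children[1]
  expect_identical(asc$nodes[[first]]$label, "D")  # leaf count 1 before 3

  for (t in yule_corpus(8, 5, 20)) {
    before <- tree_clades(t)
    asc <- ladderize(t, "ascending")
    expect_identical(tree_clades(asc), before)
    expect_same_tree(ladderize(asc, "ascending"), asc)  # idempotent
    for (id in seq_len(n_nodes(asc))) {
      ch <- asc$nodes[[id]]$children
      if (length(ch) > 1) {
        counts <- vapply(ch, function(c) count_leaves(asc, c), integer(1))
        expect_true(all(diff(counts) >= 0))
      }
    }
    desc <- ladderize(t, "descending")
    for (id in seq_len(n_nodes(desc))) {
      ch <- desc$nodes[[id]]$children
      if (length(ch) > 1) {
        counts <- vapply(ch, function(c) count_leaves(desc, c), integer(1))
        expect_true(all(diff(counts) <= 0))
      }
    }
  }
})

test_that("collapse is an involution on internal nodes and fails on leaves", {
  t <- parse_newick("((A,B),C);")
  t2 <- set_collapsed(set_collapsed(t, 2, TRUE), 2, FALSE)
  expect_identical(t2, t)
  expect_error(set_collapsed(t, node_by_label(t, "A"), TRUE), "collapse-leaf")
})

test_that("count_leaves handles leaves, roots and generated trees", {
  t <- parse_newick("((A,B),(C,D));")
  expect_identical(count_leaves(t, node_by_label(t, "A")), 1L)
  expect_identical(count_leaves(t, t$root), 4L)
  y <- generate_yule_tree(50, 11)
  expect_identical(count_leaves(y, y$root), 50L)
  expect_error(count_leaves(t, 99L), "unknown node id")
})

test_that("random binary trees satisfy the node-count identity", {
  for (n in c(2, 5, 17, 40)) {
    y <- generate_yule_tree(n, n * 13 + 1)
    expect_identical(n_nodes(y), as.integer(2 * n - 1))
    expect_silent(validate_tree(y))
  }
})

test_that("mrca finds the smallest containing clade", {
  t <- parse_newick("(((A,B)ab,C)abc,D)r;")
  expect_identical(t$nodes[[mrca(t, c("A", "B"))]]$label, "ab")
  expect_identical(t$nodes[[mrca(t, c("A", "C"))]]$label, "abc")
  expect_identical(t$nodes[[mrca(t, c("A", "D"))]]$label, "r")
  expect_identical(mrca(t, "A"), node_by_label(t, "A"))
  expect_error(mrca(t, c("A", "ZZ")), "unknown label")
})
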