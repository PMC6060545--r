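#' @title Rooted tree data model
#' @description
#' Trees are stored as plain R lists of class `"ptree"`: a `nodes` list
#' indexed by integer node id (ids are contiguous, `1..N`), a `root` id and
#' an optional `name`.  Each node is itself a list with fields
#' `id`, `label`, `branch_length` (length of the branch *subtending* the
#' node, `NA` when absent), `tags` (character vector of branch category
#' markers), `children` (ordered integer vector — child order is
#' significant and preserved by every operation except [ladderize()] and
#' tanglegram reordering), `parent` (`NA` for the root), `collapsed`,
#' `hidden`, `payload` (open named list for results computed by
#' [traverse_and_compute()]) and `metadata` (named list holding parsed
#' `[&key=value]` comment blocks).
#'
#' Branches are identified with their child node: every non-root node has
#' exactly one subtending branch, and the root has none.
#' @name ptree
NULL

new_tree_node <- function(id, label = "", branch_length = NA_real_,
                          parent = NA_integer_) {
  list(id = as.integer(id), label = label,
       branch_length = as.numeric(branch_length),
       tags = character(0),
       children = integer(0), parent = as.integer(parent),
       collapsed = FALSE, hidden = FALSE,
       payload = list(), metadata = list())
}

new_tree <- function(nodes, root, name = "") {
  structure(list(root = as.integer(root), nodes = nodes, name = name),
            class = "ptree")
}

#' Test whether an object is a phylodraw tree
#' @param x object
#' @return logical
#' @export
is_ptree <- function(x) inherits(x, "ptree")

#' Number of nodes in a tree
#' @param tree a `ptree`
#' @return integer node count
#' @export
n_nodes <- function(tree) length(tree$nodes)

#' Node ids of all leaves, in depth-first (child-order) sequence
#' @param tree a `ptree`
#' @return integer vector of leaf ids
#' @export
leaf_ids <- function(tree) {
  out <- integer(0)
  walk <- function(id) {
    ch <- tree$nodes[[id]]$children
    if (length(ch) == 0) out <<- c(out, id)
    else for (c in ch) walk(c)
  }
  walk(tree$root)
  out
}

#' Leaf labels in depth-first sequence
#' @param tree a `ptree`
#' @return character vector
#' @export
leaf_labels <- function(tree) {
  vapply(leaf_ids(tree), function(i) tree$nodes[[i]]$label, character(1))
}

#' Is a node a leaf?
#' @param tree a `ptree`
#' @param node_id integer node id
#' @return logical
#' @export
is_leaf <- function(tree, node_id) {
  stop_unknown_id(tree, node_id)
  length(tree$nodes[[node_id]]$children) == 0
}

stop_unknown_id <- function(tree, node_id) {
  if (length(node_id) != 1 || is.na(node_id) ||
      node_id < 1 || node_id > n_nodes(tree))
    stop("unknown node id: ", node_id, call. = FALSE)
  invisible(TRUE)
}

#' Find a node id by its label
#' @param tree a `ptree`
#' @param label node label to look for
#' @return integer id of the first node carrying `label`, or `NA`
#' @export
node_by_label <- function(tree, label) {
  for (nd in tree$nodes) if (identical(nd$label, label)) return(nd$id)
  NA_integer_
}

#' All node ids in the subtree rooted at a node (preorder, including it)
#' @param tree a `ptree`
#' @param node_id subtree root id
#' @return integer vector of ids
#' @export
subtree_ids <- function(tree, node_id) {
  stop_unknown_id(tree, node_id)
  out <- integer(0)
  walk <- function(id) {
    out <<- c(out, id)
    for (c in tree$nodes[[id]]$children) walk(c)
  }
  walk(node_id)
  out
}

#' Validate the structural invariants of a tree
#'
#' Checks that exactly one node is parentless (the root), that parent/child
#' links agree, that every child id exists, and that the graph is connected
#' and acyclic (every node reachable from the root exactly once).
#'
#' @param tree a `ptree`
#' @return `tree`, invisibly; stops on violation
#' @export
validate_tree <- function(tree) {
  if (!is_ptree(tree)) stop("not a ptree", call. = FALSE)
  n <- n_nodes(tree)
  roots <- which(vapply(tree$nodes, function(nd) is.na(nd$parent), logical(1)))
  if (length(roots) != 1)
    stop("tree must have exactly one parentless node, found ",
         length(roots), call. = FALSE)
  if (roots != tree$root) stop("root field does not match parentless node",
                               call. = FALSE)
  for (nd in tree$nodes) {
    for (c in nd$children) {
      if (c < 1 || c > n) stop("child id ", c, " not in node table",
                               call. = FALSE)
      if (!identical(tree$nodes[[c]]$parent, nd$id))
        stop("parent/child link mismatch at node ", c, call. = FALSE)
    }
    if (nd$collapsed && length(nd$children) == 0)
      stop("collapsed=TRUE on a leaf (node ", nd$id, ")", call. = FALSE)
  }
  seen <- subtree_ids(tree, tree$root)
  if (length(seen) != n || anyDuplicated(seen))
    stop("tree is not connected/acyclic", call. = FALSE)
  invisible(tree)
}

#' Traverse a tree and compute per-node metadata
#'
#' Visits every non-hidden node exactly once, in preorder (parent before its
#' children, children in stored order) or postorder (children before the
#' parent).  The visitor receives the node and the *current* tree — in
#' postorder the children it sees already carry any payload the visitor
#' stored on them — and may return an updated node to be written back.  The
#' visitor may modify `payload`, `tags` or `label`, but not the topology
#' fields (`id`, `parent`, `children`): doing so raises
#' `"traversal-mutation"`.  Subtrees rooted at a hidden node are skipped
#' entirely; collapsed (but not hidden) subtrees are traversed normally.
#'
#' @param tree a `ptree`
#' @param order `"preorder"` or `"postorder"`
#' @param visitor `function(node, tree)` returning an updated node, or
#'   `NULL` for no change
#' @return the traversed tree (for chaining)
#' @examples
#' t <- parse_newick("((A,B),C);")
#' t <- traverse_and_compute(t, "postorder", function(node, tree) {
#'   node$payload$leaves <- if (length(node$children) == 0) 1L else
#'     sum(vapply(node$children,
#'                function(c) tree$nodes[[c]]$payload$leaves, integer(1)))
#'   node
#' })
#' t$nodes[[t$root]]$payload$leaves  # 3
#' @export
traverse_and_compute <- function(tree,
                                 order = c("postorder", "preorder"),
                                 visitor) {
  order <- match.arg(order)
  validate_tree(tree)
  env <- new.env(parent = emptyenv())
  env$tree <- tree
  visit <- function(id) {
    node <- env$tree$nodes[[id]]
    res <- visitor(node, env$tree)
    if (!is.null(res)) {
      if (!identical(res$id, node$id) ||
          !identical(res$parent, node$parent) ||
          !identical(res$children, node$children))
        stop("traversal-mutation: visitor altered topology at node ",
             id, call. = FALSE)
      env$tree$nodes[[id]] <- res
    }
  }
  walk <- function(id) {
    node <- env$tree$nodes[[id]]
    if (node$hidden) return(invisible(NULL))
    if (order == "preorder") visit(id)
    for (c in node$children)
      if (!env$tree$nodes[[c]]$hidden) walk(c)
    if (order == "postorder") visit(id)
  }
  walk(tree$root)
  env$tree
}

#' Count leaf descendants of a node
#'
#' A leaf counts itself as 1; hidden/collapsed flags are ignored (this is a
#' topological count).
#'
#' @param tree a `ptree`
#' @param node_id node id (defaults to the root)
#' @return integer
#' @export
count_leaves <- function(tree, node_id = tree$root) {
  stop_unknown_id(tree, node_id)
  ch <- tree$nodes[[node_id]]$children
  if (length(ch) == 0) return(1L)
  sum(vapply(ch, function(c) count_leaves(tree, c), integer(1)))
}

#' Ladderize a tree
#'
#' Stably reorders every internal node's children by subtree leaf count —
#' non-decreasing for `"ascending"`, non-increasing for `"descending"`.
#' The set of clades (the topology) is unchanged; only child order moves.
#'
#' @param tree a `ptree`
#' @param direction `"ascending"` or `"descending"`
#' @return the reordered tree
#' @export
ladderize <- function(tree, direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  counts <- integer(n_nodes(tree))
  fill <- function(id) {
    ch <- tree$nodes[[id]]$children
    counts[id] <<- if (length(ch) == 0) 1L else {
      for (c in ch) fill(c)
      sum(counts[ch])
    }
  }
  fill(tree$root)
  for (id in seq_len(n_nodes(tree))) {
    ch <- tree$nodes[[id]]$children
    if (length(ch) > 1) {
      key <- counts[ch]
      ord <- order(if (direction == "ascending") key else -key)
      tree$nodes[[id]]$children <- ch[ord]
    }
  }
  tree
}

#' Collapse or expand an internal node
#'
#' Collapsing replaces the subtree, in layouts, by a single leaf slot and a
#' boundary glyph; the topology is untouched and the descendants remain in
#' the tree.  Collapsing a leaf is an error (`"collapse-leaf"`).  When
#' collapsed nodes nest, layouts honor only the outermost one.
#'
#' @param tree a `ptree`
#' @param node_id internal node id
#' @param state logical
#' @return the updated tree
#' @export
set_collapsed <- function(tree, node_id, state) {
  stop_unknown_id(tree, node_id)
  if (is_leaf(tree, node_id))
    stop("collapse-leaf: cannot collapse a leaf (node ", node_id, ")",
         call. = FALSE)
  tree$nodes[[node_id]]$collapsed <- isTRUE(state)
  tree
}

#' Hide or show a subtree
#'
#' A hidden node and its whole subtree are removed from traversal and
#' layout entirely (unlike collapsing, which leaves a placeholder).
#'
#' @param tree a `ptree`
#' @param node_id node id
#' @param state logical
#' @return the updated tree
#' @export
set_hidden <- function(tree, node_id, state) {
  stop_unknown_id(tree, node_id)
  tree$nodes[[node_id]]$hidden <- isTRUE(state)
  tree
}

#' Reorder the children of a node
#' @param tree a `ptree`
#' @param node_id internal node id
#' @param perm permutation of `seq_along(children)`
#' @return the updated tree
#' @export
set_child_order <- function(tree, node_id, perm) {
  stop_unknown_id(tree, node_id)
  ch <- tree$nodes[[node_id]]$children
  if (!setequal(perm, seq_along(ch)) || length(perm) != length(ch))
    stop("perm is not a permutation of the children", call. = FALSE)
  tree$nodes[[node_id]]$children <- ch[perm]
  tree
}

#' Most recent common ancestor of a set of leaf labels
#' @param tree a `ptree`
#' @param labels character vector of leaf labels
#' @return integer node id
#' @export
mrca <- function(tree, labels) {
  ids <- vapply(labels, function(l) node_by_label(tree, l), integer(1))
  if (anyNA(ids)) stop("unknown label(s): ",
                       paste(labels[is.na(ids)], collapse = ", "),
                       call. = FALSE)
  path_to_root <- function(id) {
    p <- id
    while (!is.na(tree$nodes[[id]]$parent)) {
      id <- tree$nodes[[id]]$parent
      p <- c(p, id)
    }
    p
  }
  common <- Reduce(intersect, lapply(ids, path_to_root))
  common[1]
}

#' The multiset of clades of a tree
#'
#' Each internal node contributes the sorted set of its descendant leaf
#' labels.  Used to assert that reordering operations preserve topology.
#'
#' @param tree a `ptree`
#' @return list of character vectors, sorted canonically
#' @export
tree_clades <- function(tree) {
  out <- list()
  for (id in seq_len(n_nodes(tree))) {
    if (length(tree$nodes[[id]]$children) > 0) {
      lv <- subtree_ids(tree, id)
      lv <- lv[vapply(lv, function(i)
        length(tree$nodes[[i]]$children) == 0, logical(1))]
      out[[length(out) + 1]] <-
        sort(vapply(lv, function(i) tree$nodes[[i]]$label, character(1)))
    }
  }
  out[order(vapply(out, paste, character(1), collapse = "\r"))]
}

#' @export
print.ptree <- function(x, ...) {
  nl <- length(leaf_ids(x))
  cat(sprintf("<ptree> %d nodes, %d leaves%s\n", n_nodes(x), nl,
              if (nzchar(x$name)) paste0(", name: ", x$name) else ""))
  invisible(x)
}
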