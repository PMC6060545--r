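#' @title Seeded random tree and tanglegram generation
#' @description
#' A Yule (pure-birth) simulator plus orientation/label scramblers drive
#' the package's property tests; the same seed always reproduces the same
#' object, and the caller's RNG state is left untouched.
#' @name fixtures
NULL

with_preserved_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Simulate a Yule (pure-birth) tree
#'
#' Starting from a root with two lineages, a uniformly chosen extant
#' lineage splits at each event; exponential(`rate * k`) waiting times
#' (k = current lineage count) accrue on every extant pendant branch, so
#' all branch lengths are strictly positive.  Leaves are labelled
#' `L1..Ln` in depth-first order; the root has no branch length.  The
#' same seed yields the identical tree.
#'
#' @param n_leaves number of leaves (>= 2)
#' @param seed integer RNG seed
#' @param rate birth rate (> 0), the scale of the waiting times
#' @return a binary `ptree` with `2 * n_leaves - 1` nodes
#' @export
generate_yule_tree <- function(n_leaves, seed, rate = 1) {
  if (n_leaves < 2) stop("n_leaves must be >= 2", call. = FALSE)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  with_preserved_seed(seed, function() {
    nodes <- list(new_tree_node(1L))
    pending <- numeric(2 * n_leaves - 1)
    spawn <- function(parent) {
      id <- length(nodes) + 1L
      nodes[[id]] <<- new_tree_node(id, parent = parent)
      nodes[[parent]]$children <<- c(nodes[[parent]]$children, id)
      id
    }
    extant <- c(spawn(1L), spawn(1L))
    while (length(extant) < n_leaves) {
      k <- length(extant)
      dt <- stats::rexp(1, rate * k)
      pending[extant] <- pending[extant] + dt
      pick <- extant[sample.int(k, 1)]
      nodes[[pick]]$branch_length <- pending[pick]
      extant <- c(setdiff(extant, pick), spawn(pick), spawn(pick))
    }
    dt <- stats::rexp(1, rate * length(extant))
    pending[extant] <- pending[extant] + dt
    for (id in extant) nodes[[id]]$branch_length <- pending[id]
    tree <- renumber_preorder(new_tree(nodes, 1L))
    lv <- leaf_ids(tree)
    for (i in seq_along(lv))
      tree$nodes[[lv[i]]]$label <- paste0("L", i)
    validate_tree(tree)
  })
}

# renumber node ids to depth-first preorder, so that ids are stable under
# a write -> parse round trip (parsers assign preorder ids)
renumber_preorder <- function(tree) {
  ord <- subtree_ids(tree, tree$root)
  map <- integer(n_nodes(tree))
  map[ord] <- seq_along(ord)
  nodes <- vector("list", length(ord))
  for (old in seq_along(map)) {
    nd <- tree$nodes[[old]]
    nd$id <- map[old]
    if (!is.na(nd$parent)) nd$parent <- map[nd$parent]
    nd$children <- map[nd$children]
    nodes[[map[old]]] <- nd
  }
  new_tree(nodes, map[tree$root], tree$name)
}

#' Randomly flip child orders
#'
#' Each internal node's child list is independently reversed with
#' probability 1/2.  The clade set (topology) is unchanged.
#'
#' @param tree a `ptree`
#' @param seed integer RNG seed
#' @return the reordered tree
#' @export
scramble_orientation <- function(tree, seed) {
  with_preserved_seed(seed, function() {
    for (id in seq_len(n_nodes(tree))) {
      ch <- tree$nodes[[id]]$children
      if (length(ch) > 1 && stats::runif(1) < 0.5)
        tree$nodes[[id]]$children <- rev(ch)
    }
    tree
  })
}

#' Generate a tanglegram test instance
#'
#' The left tree is a Yule tree; the right tree is a copy whose leaf
#' labels are perturbed by `n_leaf_swaps` random pairwise swaps and whose
#' child orders are scrambled.  The matching is the identity on labels,
#' so with zero swaps the minimized crossing count is 0.
#'
#' @param n_leaves leaves per tree (>= 3)
#' @param seed integer RNG seed
#' @param n_leaf_swaps number of random leaf-label swaps applied to the
#'   right tree
#' @param rate Yule birth rate
#' @return a [tanglegram()]
#' @export
generate_tangled_pair <- function(n_leaves, seed, n_leaf_swaps = 0,
                                  rate = 1) {
  if (n_leaves < 3) stop("n_leaves must be >= 3", call. = FALSE)
  left <- generate_yule_tree(n_leaves, seed, rate)
  right <- left
  if (n_leaf_swaps > 0) {
    right <- with_preserved_seed(seed + 1L, function() {
      lv <- leaf_ids(right)
      for (i in seq_len(n_leaf_swaps)) {
        pair <- sample(lv, 2)
        tmp <- right$nodes[[pair[1]]]$label
        right$nodes[[pair[1]]]$label <- right$nodes[[pair[2]]]$label
        right$nodes[[pair[2]]]$label <- tmp
      }
      right
    })
  }
  right <- scramble_orientation(right, seed + 2L)
  tanglegram(left, right)
}
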