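#' Create a multi-category branch selection state
#'
#' A selection state binds a set of named categories to the branches of a
#' tree.  Branches are identified with their child node id; the root has no
#' subtending branch and is never selectable.  Registered callbacks are
#' invoked, in registration order, exactly once after every
#' [apply_selection()] update.
#'
#' @param tree the `ptree` the state is bound to
#' @param categories ordered character vector of category names
#' @return an object of class `"selection_state"`
#' @export
selection_state <- function(tree, categories = c("test", "reference")) {
  validate_tree(tree)
  structure(list(categories = categories,
                 assignment = list(),   # "id" -> character vector
                 callbacks = list(),
                 n_tree_nodes = n_nodes(tree)),
            class = "selection_state")
}

#' Register a selection-update callback
#'
#' The function is appended to the callback registry and will be called as
#' `fn(tree, state)` with the post-update state after every subsequent
#' [apply_selection()].
#'
#' @param state a [selection_state()]
#' @param fn a function of `(tree, state)`
#' @return the updated state
#' @export
register_callback <- function(state, fn) {
  stopifnot(inherits(state, "selection_state"), is.function(fn))
  state$callbacks[[length(state$callbacks) + 1]] <- fn
  state
}

#' Branch ids currently assigned to a category
#' @param state a [selection_state()]
#' @param category category name (default: any category)
#' @return integer vector of node ids (each naming its subtending branch)
#' @export
selected_branches <- function(state, category = NULL) {
  keep <- vapply(state$assignment, function(cats) {
    if (is.null(category)) length(cats) > 0 else category %in% cats
  }, logical(1))
  if (length(keep) == 0) return(integer(0))
  sort(as.integer(names(state$assignment)[keep]))
}

resolve_selection_ids <- function(tree, mode, anchor, layout) {
  switch(mode,
    branch = {
      stop_unknown_id(tree, anchor)
      if (anchor == tree$root)
        stop("the root has no subtending branch", call. = FALSE)
      anchor
    },
    clade = {
      stop_unknown_id(tree, anchor)
      setdiff(subtree_ids(tree, anchor), tree$root)
    },
    path_to_root = {
      stop_unknown_id(tree, anchor)
      ids <- integer(0)
      id <- anchor
      while (!is.na(tree$nodes[[id]]$parent)) {
        ids <- c(ids, id)
        id <- tree$nodes[[id]]$parent
      }
      ids
    },
    all_external = leaf_ids(tree),
    all_internal = {
      ids <- which(vapply(tree$nodes, function(nd)
        length(nd$children) > 0, logical(1)))
      setdiff(ids, tree$root)
    },
    near_point = {
      if (is.null(layout))
        stop("near_point selection requires a layout", call. = FALSE)
      if (!is.list(anchor) || is.null(anchor$point) || is.null(anchor$radius))
        stop("near_point anchor must be list(point = c(x, y), radius = r)",
             call. = FALSE)
      branches_near_point(tree, layout, anchor$point, anchor$radius)
    },
    stop("unknown selection mode: ", mode, call. = FALSE)
  )
}

#' Apply a selection operation
#'
#' The selection mechanisms:
#' * `branch` — the single branch subtending `anchor`;
#' * `clade` — every branch in `anchor`'s subtree *plus* `anchor`'s own
#'   subtending branch (so a clade of k nodes selects k branches);
#' * `path_to_root` — the branches on the path from `anchor` up to and
#'   including the root's child on that path;
#' * `all_external` — every leaf branch;
#' * `all_internal` — every internal, non-root branch;
#' * `near_point` — branches whose drawn segment lies within Euclidean
#'   `radius` of a point in layout coordinates; `anchor` must be
#'   `list(point = c(x, y), radius = r)` and `layout` must be supplied.
#'
#' After the assignment is updated, every registered callback is invoked
#' once with `(tree, new_state)`.
#'
#' @param tree the bound `ptree`
#' @param state a [selection_state()]
#' @param mode selection mechanism (see above)
#' @param anchor node id, or a point spec for `near_point`
#' @param category category name; must be one of the state's categories
#' @param action `"add"`, `"remove"` or `"toggle"`
#' @param layout a layout result, required for `near_point`
#' @return the updated state
#' @export
apply_selection <- function(tree, state,
                            mode = c("branch", "clade", "path_to_root",
                                     "all_external", "all_internal",
                                     "near_point"),
                            anchor = NULL, category,
                            action = c("add", "remove", "toggle"),
                            layout = NULL) {
  mode <- match.arg(mode)
  action <- match.arg(action)
  stopifnot(inherits(state, "selection_state"))
  if (!category %in% state$categories)
    stop("unknown category: ", category, call. = FALSE)
  ids <- resolve_selection_ids(tree, mode, anchor, layout)
  for (id in ids) {
    key <- as.character(id)
    cur <- state$assignment[[key]]
    if (is.null(cur)) cur <- character(0)
    new <- switch(action,
      add    = union(cur, category),
      remove = setdiff(cur, category),
      toggle = if (category %in% cur) setdiff(cur, category)
               else union(cur, category))
    if (length(new) == 0) state$assignment[[key]] <- NULL
    else state$assignment[[key]] <- new
  }
  for (fn in state$callbacks) fn(tree, state)
  state
}

#' Serialize a selection as annotated Newick
#'
#' Emits the bound tree in the `hyphy_tags` dialect with each selected
#' branch carrying its category as a `{category}` block; unselected
#' branches carry nothing.  A branch assigned to two or more categories
#' needs `category_order` (highest priority first) to pick one tag;
#' without it this raises `"ambiguous-tag"`.  Parsing the output with the
#' `hyphy_tags` dialect reproduces the assignment.
#'
#' @param tree the bound `ptree`
#' @param state a [selection_state()]
#' @param category_order optional priority order over category names
#' @param precision branch-length digits, as in [write_newick()]
#' @return an annotated Newick string
#' @examples
#' t <- parse_newick("((A,B),C);")
#' s <- selection_state(t)
#' s <- apply_selection(t, s, "clade", anchor = 2, category = "test")
#' s <- apply_selection(t, s, "branch", anchor = node_by_label(t, "C"),
#'                      category = "reference")
#' serialize_selection(t, s)  # "((A{test},B{test}){test},C{reference});"
#' @export
serialize_selection <- function(tree, state, category_order = NULL,
                                precision = 6) {
  stopifnot(inherits(state, "selection_state"))
  for (id in seq_len(n_nodes(tree))) tree$nodes[[id]]$tags <- character(0)
  for (key in names(state$assignment)) {
    cats <- state$assignment[[key]]
    tag <- if (length(cats) == 1) cats else {
      if (is.null(category_order))
        stop("ambiguous-tag: branch ", key, " carries {",
             paste(cats, collapse = ", "),
             "} and no category_order was given", call. = FALSE)
      hit <- category_order[category_order %in% cats]
      if (length(hit) == 0)
        stop("ambiguous-tag: category_order resolves none of {",
             paste(cats, collapse = ", "), "}", call. = FALSE)
      hit[1]
    }
    tree$nodes[[as.integer(key)]]$tags <- tag
  }
  write_newick(tree, newick_dialect("hyphy_tags"), precision = precision)
}

#' Recover a selection state from an annotated tree
#'
#' The inverse of [serialize_selection()]: branch tags stored on a tree
#' (e.g. parsed under the `hyphy_tags` dialect) become the assignment of a
#' fresh selection state.
#'
#' @param tree a `ptree` whose nodes carry `tags`
#' @param categories category universe; defaults to the tags present
#' @return a [selection_state()]
#' @export
selection_from_tags <- function(tree, categories = NULL) {
  seen <- unique(unlist(lapply(tree$nodes, function(nd) nd$tags)))
  if (is.null(categories)) categories <- sort(seen)
  state <- selection_state(tree, categories)
  for (nd in tree$nodes) {
    if (length(nd$tags) > 0 && nd$id != tree$root)
      state$assignment[[as.character(nd$id)]] <- nd$tags
  }
  state
}
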