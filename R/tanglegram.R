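#' Build a tanglegram
#'
#' A tanglegram is two trees drawn side by side with links between matched
#' leaves; the number of link crossings measures the discordance between
#' the two child orderings.  The matching may be many-to-many, and leaves
#' may be unmatched (they contribute no links).  The child order stored in
#' each tree *is* the orientation state: [minimize_crossings()] returns a
#' tanglegram whose trees have reordered children.
#'
#' @param left,right `ptree` objects
#' @param matching a two-column data frame or matrix of (left label, right
#'   label) pairs, or `NULL` for the identity matching on shared leaf
#'   labels
#' @return an object of class `"tanglegram"`
#' @export
tanglegram <- function(left, right, matching = NULL) {
  validate_tree(left); validate_tree(right)
  if (is.null(matching)) {
    shared <- intersect(leaf_labels(left), leaf_labels(right))
    matching <- cbind(shared, shared)
  }
  matching <- as.matrix(matching)
  if (ncol(matching) != 2)
    stop("matching must have two columns", call. = FALSE)
  to_ids <- function(tree, labels, side) {
    lv <- leaf_ids(tree)
    names(lv) <- vapply(lv, function(i) tree$nodes[[i]]$label, character(1))
    ids <- lv[labels]
    if (anyNA(ids))
      stop("matching references unknown ", side, " leaf label(s): ",
           paste(unique(labels[is.na(ids)]), collapse = ", "),
           call. = FALSE)
    unname(ids)
  }
  links <- cbind(left = to_ids(left, matching[, 1], "left"),
                 right = to_ids(right, matching[, 2], "right"))
  structure(list(left = left, right = right, links = links),
            class = "tanglegram")
}

#' Read a leaf matching from a two-column tab-separated file
#'
#' Lines hold `left_label<TAB>right_label`; blank lines and `#` comments
#' are skipped.
#'
#' @param path file path
#' @return a two-column character matrix
#' @export
read_matching <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2))
    stop("matching file must have two tab-separated columns", call. = FALSE)
  cbind(vapply(parts, `[`, character(1), 1),
        vapply(parts, `[`, character(1), 2))
}

# depth-first rank of every leaf under the current child order, by node id
leaf_ranks <- function(tree) {
  lv <- leaf_ids(tree)
  r <- integer(n_nodes(tree))
  r[lv] <- seq_along(lv)
  r
}

#' Count link crossings of a tanglegram
#'
#' With left leaves at ranks `1..nL` (depth-first under the current child
#' order) and right leaves likewise, two links `(a, b)` and `(c, d)` cross
#' iff `(rank(a) - rank(c)) * (rank(b) - rank(d)) < 0`; links sharing an
#' endpoint never cross.
#'
#' @param tg a [tanglegram()]
#' @return integer crossing count
#' @export
count_crossings <- function(tg) {
  stopifnot(inherits(tg, "tanglegram"))
  rl <- leaf_ranks(tg$left)[tg$links[, 1]]
  rr <- leaf_ranks(tg$right)[tg$links[, 2]]
  m <- length(rl)
  if (m < 2) return(0L)
  total <- 0L
  for (i in seq_len(m - 1)) {
    da <- rl[i] - rl[(i + 1):m]
    db <- rr[i] - rr[(i + 1):m]
    total <- total + sum(da * db < 0)
  }
  as.integer(total)
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1))
    for (pos in seq_len(k))
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
  out
}

# all permutations of 1..k with the identity first, so that taking the
# first minimum breaks ties toward the input child order
perms_identity_first <- function(k) {
  ps <- all_permutations(k)
  idx <- which(vapply(ps, function(p) all(p == seq_len(k)), logical(1)))[1]
  c(ps[idx], ps[-idx])
}

# pairs (a in x, b in y) with a > b
pair_inversions <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) return(0L)
  as.integer(sum(vapply(x, function(a) sum(y < a), numeric(1))))
}

# One-sided exact optimum: reorder the children of every internal node of
# the free tree to minimize crossings against the fixed side.  Any two
# links with distinct free-side leaves separate at exactly one free-tree
# node (their LCA), and whether they cross is decided solely by the order
# of that node's child blocks and the links' fixed-side ranks — so the
# per-node choices are independent and a bottom-up pass is exact, for any
# node degree (each node's child permutations are enumerated, hence the
# degree cap).
dp_one_side <- function(tg, free = c("right", "left"), degree_cap = 8) {
  free <- match.arg(free)
  free_tree <- if (free == "right") tg$right else tg$left
  fixed_tree <- if (free == "right") tg$left else tg$right
  free_col <- if (free == "right") 2 else 1
  fixed_ranks <- leaf_ranks(fixed_tree)

  # fixed-side ranks of the links hanging off each free leaf
  link_ranks <- vector("list", n_nodes(free_tree))
  for (i in seq_len(nrow(tg$links))) {
    fid <- tg$links[i, free_col]
    link_ranks[[fid]] <- c(link_ranks[[fid]],
                           fixed_ranks[tg$links[i, 3 - free_col]])
  }

  total <- 0L
  walk <- function(id) {
    ch <- free_tree$nodes[[id]]$children
    if (length(ch) == 0) return(sort(link_ranks[[id]]))
    blocks <- lapply(ch, walk)
    if (length(ch) > 1) {
      if (length(ch) > degree_cap)
        stop("degree-cap: node ", id, " has ", length(ch),
             " children (cap ", degree_cap, ")", call. = FALSE)
      k <- length(ch)
      inv <- matrix(0L, k, k)
      for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
        inv[i, j] <- pair_inversions(blocks[[i]], blocks[[j]])
      perms <- perms_identity_first(k)
      costs <- vapply(perms, function(p) {
        cost <- 0L
        for (a in seq_len(k - 1)) for (b in (a + 1):k)
          cost <- cost + inv[p[a], p[b]]
        cost
      }, integer(1))
      best <- min(costs)
      choice <- which.min(costs)   # first minimum; identity is first
      total <<- total + best
      if (choice != 1L) {
        p <- perms[[choice]]
        free_tree$nodes[[id]]$children <<- ch[p]
        blocks <- blocks[p]
      }
    }
    sort(unlist(blocks))
  }
  walk(free_tree$root)
  if (free == "right") tg$right <- free_tree else tg$left <- free_tree
  list(tg = tg, crossings = as.integer(total))
}

orientation_space <- function(tree, degree_cap) {
  ids <- which(vapply(tree$nodes, function(nd)
    length(nd$children) > 1, logical(1)))
  perms <- lapply(ids, function(id) {
    k <- length(tree$nodes[[id]]$children)
    if (k > degree_cap)
      stop("degree-cap: node ", id, " has ", k, " children (cap ",
           degree_cap, ")", call. = FALSE)
    perms_identity_first(k)
  })
  list(ids = ids, perms = perms,
       size = prod(vapply(perms, length, numeric(1))))
}

apply_orientation <- function(tree, space, counter) {
  for (i in seq_along(space$ids))
    tree <- set_child_order(tree, space$ids[i], space$perms[[i]][[counter[i]]])
  tree
}

# iterate a mixed-radix counter; returns NULL after the last combination
next_counter <- function(counter, radices) {
  for (i in seq_along(counter)) {
    if (counter[i] < radices[i]) {
      counter[i] <- counter[i] + 1L
      return(counter)
    }
    counter[i] <- 1L
  }
  NULL
}

#' Minimize tanglegram crossings
#'
#' Reorders children (which never changes the topology) to minimize link
#' crossings.  With `free_side = "right"` the left tree is fixed and the
#' optimum over all child reorderings of the right tree is found by an
#' exact bottom-up dynamic program (per-node child-order choices are
#' independent given the fixed side; see [dp_one_side] notes).  With
#' `free_side = "both"` every orientation of the left tree is enumerated
#' and the right tree is optimized by the DP for each, which is globally
#' exact; when the left orientation space exceeds `max_enumeration` the
#' solver falls back to alternating one-sided passes to a fixed point (a
#' heuristic, reported via a message).  Ties are broken toward the input
#' orientation.
#'
#' @param tg a [tanglegram()]
#' @param free_side `"right"` or `"both"`
#' @param degree_cap maximum children per free internal node (the DP
#'   enumerates each node's child permutations); larger degrees raise
#'   `"degree-cap"`
#' @param max_enumeration largest left-side orientation space enumerated
#'   exactly in `"both"` mode
#' @return `list(tg = reordered tanglegram, crossings = minimum count)`
#' @export
minimize_crossings <- function(tg, free_side = c("right", "both"),
                               degree_cap = 8, max_enumeration = 65536) {
  free_side <- match.arg(free_side)
  stopifnot(inherits(tg, "tanglegram"))
  if (free_side == "right") return(dp_one_side(tg, "right", degree_cap))

  space <- orientation_space(tg$left, degree_cap)
  if (space$size <= max_enumeration) {
    counter <- rep(1L, length(space$ids))
    radices <- vapply(space$perms, length, integer(1))
    best <- NULL
    repeat {
      cand <- tg
      cand$left <- apply_orientation(tg$left, space, counter)
      res <- dp_one_side(cand, "right", degree_cap)
      if (is.null(best) || res$crossings < best$crossings) best <- res
      if (best$crossings == 0) break
      counter <- next_counter(counter, radices)
      if (is.null(counter)) break
    }
    return(best)
  }

  message("left orientation space too large (", space$size,
          "); using alternating one-sided passes (heuristic)")
  cur <- list(tg = tg, crossings = count_crossings(tg))
  repeat {
    step <- dp_one_side(cur$tg, "right", degree_cap)
    step <- dp_one_side(step$tg, "left", degree_cap)
    if (step$crossings >= cur$crossings) break
    cur <- step
  }
  cur
}

#' Exact minimum crossings by exhaustive enumeration
#'
#' The brute-force oracle: every orientation assignment of the free
#' side(s) is enumerated and [count_crossings()] evaluated.  Intended for
#' small instances; the search space is capped.
#'
#' @param tg a [tanglegram()]
#' @param free_side `"right"` or `"both"`
#' @param degree_cap as in [minimize_crossings()]
#' @param max_space largest number of orientation assignments searched
#' @return integer minimum crossing count
#' @export
brute_force_min_crossings <- function(tg, free_side = c("right", "both"),
                                      degree_cap = 8, max_space = 2^18) {
  free_side <- match.arg(free_side)
  stopifnot(inherits(tg, "tanglegram"))
  sides <- if (free_side == "right") "right" else c("left", "right")
  spaces <- lapply(sides, function(s)
    orientation_space(tg[[s]], degree_cap))
  total <- prod(vapply(spaces, function(sp) sp$size, numeric(1)))
  if (total > max_space)
    stop("search space too large: ", total, " orientation assignments",
         call. = FALSE)
  ids <- unlist(lapply(seq_along(sides), function(i)
    rep(i, length(spaces[[i]]$ids))))
  radices <- unlist(lapply(spaces, function(sp)
    vapply(sp$perms, length, integer(1))))
  if (length(radices) == 0) return(count_crossings(tg))
  counter <- rep(1L, length(radices))
  best <- Inf
  repeat {
    cand <- tg
    off <- 0
    for (i in seq_along(sides)) {
      ni <- length(spaces[[i]]$ids)
      if (ni > 0)
        cand[[sides[i]]] <- apply_orientation(
          tg[[sides[i]]], spaces[[i]], counter[(off + 1):(off + ni)])
      off <- off + ni
    }
    best <- min(best, count_crossings(cand))
    if (best == 0) break
    counter <- next_counter(counter, radices)
    if (is.null(counter)) break
  }
  as.integer(best)
}

#' @export
print.tanglegram <- function(x, ...) {
  cat(sprintf("<tanglegram> %d + %d leaves, %d links, %d crossings\n",
              length(leaf_ids(x$left)), length(leaf_ids(x$right)),
              nrow(x$links), count_crossings(x)))
  invisible(x)
}
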