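#' @title Tree layout computation
#' @description
#' Layouts assign 2-D coordinates to every *visible* node.  A node is
#' visible when neither it nor any ancestor is hidden and no proper
#' ancestor is collapsed: the outermost collapsed node of a nested group
#' is itself visible and occupies exactly one leaf slot; its descendants
#' are not laid out.  Fixed drawing conventions: in rectangular layouts x
#' grows from the root toward the leaves and y grows downward, leaf by
#' leaf; in radial layouts angles grow counter-clockwise from the positive
#' x-axis and are stored in radians within `[0, 2*pi)`.  Internal nodes
#' sit at the arithmetic mean of their visible children's y (or angle).
#' @name layout
NULL

# visible children of a visible node (empty when the node is collapsed,
# i.e. it acts as a leaf slot)
visible_children <- function(tree, id) {
  nd <- tree$nodes[[id]]
  if (nd$collapsed) return(integer(0))
  ch <- nd$children
  ch[!vapply(ch, function(c) tree$nodes[[c]]$hidden, logical(1))]
}

# depth-first visible leaf slots (true leaves + outermost collapsed nodes)
visible_leaf_slots <- function(tree) {
  out <- integer(0)
  walk <- function(id) {
    if (tree$nodes[[id]]$hidden) return(invisible(NULL))
    ch <- visible_children(tree, id)
    if (length(ch) == 0) out <<- c(out, id)
    else for (c in ch) walk(c)
  }
  walk(tree$root)
  out
}

visible_ids <- function(tree) {
  out <- integer(0)
  walk <- function(id) {
    if (tree$nodes[[id]]$hidden) return(invisible(NULL))
    out <<- c(out, id)
    for (c in visible_children(tree, id)) walk(c)
  }
  walk(tree$root)
  out
}

new_layout <- function(mode, scale_mode, coordinates, edge_paths,
                       collapsed_boundaries, extents, leaf_order, params,
                       n_tree_nodes) {
  structure(list(mode = mode, scale_mode = scale_mode,
                 coordinates = coordinates, edge_paths = edge_paths,
                 collapsed_boundaries = collapsed_boundaries,
                 extents = extents, leaf_order = leaf_order,
                 params = params, n_tree_nodes = n_tree_nodes),
            class = "tree_layout")
}

# cumulative distance from the root for every visible node:
# phylogram = summed branch lengths (absent length -> 0, with one warning),
# cladogram = edge-count depth
root_distances <- function(tree, vis, scale_mode) {
  d <- rep(NA_real_, n_nodes(tree))
  warned <- FALSE
  walk <- function(id, acc) {
    d[id] <<- acc
    for (c in visible_children(tree, id)) {
      step <- if (scale_mode == "cladogram") 1 else {
        bl <- tree$nodes[[c]]$branch_length
        if (is.na(bl)) {
          if (!warned) {
            warning("missing branch length treated as 0 in phylogram mode",
                    call. = FALSE)
            warned <<- TRUE
          }
          0
        } else bl
      }
      walk(c, acc + step)
    }
  }
  walk(tree$root, 0)
  d
}

#' Rectangular (left-to-right) tree layout
#'
#' Visible leaf slots get `y = 0, s, 2s, ...` in depth-first child order;
#' every visible internal node's y is the mean of its visible children's y.
#' In `phylogram` mode x is the cumulative branch length from the root,
#' rescaled so the deepest visible node sits at `width`; in `cladogram`
#' mode internal x is edge-count depth over the maximum depth times
#' `width`, and every leaf slot is pushed to `x = width`.  The root is at
#' `x = 0`.  Edge paths are axis-parallel elbows (vertical at the parent's
#' x, then horizontal to the child).  Each outermost collapsed node
#' contributes a triangular boundary wedge spanning its single leaf slot.
#'
#' @param tree a `ptree`
#' @param scale_mode `"phylogram"` or `"cladogram"`
#' @param leaf_spacing vertical distance between adjacent leaf slots (> 0)
#' @param width horizontal extent of the drawing (> 0)
#' @return a `"tree_layout"` with Cartesian `coordinates` (columns x, y)
#' @export
layout_rectangular <- function(tree,
                               scale_mode = c("phylogram", "cladogram"),
                               leaf_spacing = 1, width = 1) {
  scale_mode <- match.arg(scale_mode)
  validate_tree(tree)
  if (width <= 0 || leaf_spacing <= 0)
    stop("width and leaf_spacing must be positive", call. = FALSE)
  vis <- visible_ids(tree)
  slots <- visible_leaf_slots(tree)
  n <- n_nodes(tree)

  y <- rep(NA_real_, n)
  y[slots] <- (seq_along(slots) - 1) * leaf_spacing
  fill_y <- function(id) {
    ch <- visible_children(tree, id)
    if (length(ch) > 0) {
      for (c in ch) fill_y(c)
      y[id] <<- mean(y[ch])
    }
  }
  fill_y(tree$root)

  d <- root_distances(tree, vis, scale_mode)
  dmax <- max(d[vis])
  x <- if (dmax > 0) d / dmax * width else ifelse(is.na(d), NA_real_, 0)
  if (scale_mode == "cladogram") x[slots] <- width

  coords <- matrix(NA_real_, nrow = n, ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  coords[vis, 1] <- x[vis]
  coords[vis, 2] <- y[vis]

  edge_paths <- list()
  for (id in vis) {
    p <- tree$nodes[[id]]$parent
    if (!is.na(p)) {
      edge_paths[[as.character(id)]] <- list(
        type = "elbow",
        from = c(coords[p, 1], coords[p, 2]),
        corner = c(coords[p, 1], coords[id, 2]),
        to = c(coords[id, 1], coords[id, 2]))
    }
  }

  boundaries <- list()
  for (id in vis) {
    if (tree$nodes[[id]]$collapsed) {
      h <- 0.4 * leaf_spacing
      boundaries[[as.character(id)]] <- rbind(
        c(coords[id, 1], coords[id, 2]),
        c(width, coords[id, 2] - h),
        c(width, coords[id, 2] + h))
    }
  }

  new_layout("rectangular", scale_mode, coords, edge_paths, boundaries,
             extents = c(xmin = min(coords[vis, 1]),
                         ymin = min(coords[vis, 2]),
                         xmax = max(coords[vis, 1]),
                         ymax = max(coords[vis, 2])),
             leaf_order = slots,
             params = list(leaf_spacing = leaf_spacing, width = width),
             n_tree_nodes = n)
}

#' Radial (circular) tree layout
#'
#' The n visible leaf slots receive angles `2*pi*k/n`, `k = 0..n-1`, in
#' depth-first order; internal angles are the mean of the visible
#' children's angles.  The radial coordinate follows `scale_mode` exactly
#' as x does in [layout_rectangular()], scaled to `radius`.  Edge paths
#' are an arc at the parent's radius from the parent's angle to the
#' child's angle, followed by a radial segment outward to the child.
#'
#' @param tree a `ptree`
#' @param scale_mode `"phylogram"` or `"cladogram"`
#' @param radius radial extent of the drawing (> 0)
#' @return a `"tree_layout"` with polar `coordinates` (columns r, theta)
#' @export
layout_radial <- function(tree, scale_mode = c("phylogram", "cladogram"),
                          radius = 1) {
  scale_mode <- match.arg(scale_mode)
  validate_tree(tree)
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  vis <- visible_ids(tree)
  slots <- visible_leaf_slots(tree)
  n <- n_nodes(tree)
  nl <- length(slots)

  theta <- rep(NA_real_, n)
  theta[slots] <- 2 * pi * (seq_along(slots) - 1) / nl
  fill_theta <- function(id) {
    ch <- visible_children(tree, id)
    if (length(ch) > 0) {
      for (c in ch) fill_theta(c)
      theta[id] <<- mean(theta[ch])
    }
  }
  fill_theta(tree$root)

  d <- root_distances(tree, vis, scale_mode)
  dmax <- max(d[vis])
  r <- if (dmax > 0) d / dmax * radius else ifelse(is.na(d), NA_real_, 0)
  if (scale_mode == "cladogram") r[slots] <- radius

  coords <- matrix(NA_real_, nrow = n, ncol = 2,
                   dimnames = list(NULL, c("r", "theta")))
  coords[vis, 1] <- r[vis]
  coords[vis, 2] <- theta[vis]

  edge_paths <- list()
  for (id in vis) {
    p <- tree$nodes[[id]]$parent
    if (!is.na(p)) {
      edge_paths[[as.character(id)]] <- list(
        type = "arc_radial",
        arc = c(r = coords[p, 1], from = coords[p, 2], to = coords[id, 2]),
        seg_from = c(coords[p, 1], coords[id, 2]),
        seg_to = c(coords[id, 1], coords[id, 2]))
    }
  }

  boundaries <- list()
  for (id in vis) {
    if (tree$nodes[[id]]$collapsed) {
      half <- if (nl > 1) 0.4 * 2 * pi / nl else 0.4
      boundaries[[as.character(id)]] <- rbind(
        polar_xy(coords[id, 1], coords[id, 2]),
        polar_xy(radius, coords[id, 2] - half),
        polar_xy(radius, coords[id, 2] + half))
    }
  }

  cart <- t(vapply(vis, function(i) polar_xy(coords[i, 1], coords[i, 2]),
                   numeric(2)))
  new_layout("radial", scale_mode, coords, edge_paths, boundaries,
             extents = c(xmin = min(cart[, 1]), ymin = min(cart[, 2]),
                         xmax = max(cart[, 1]), ymax = max(cart[, 2])),
             leaf_order = slots,
             params = list(radius = radius),
             n_tree_nodes = n)
}

polar_xy <- function(r, theta) c(r * cos(theta), r * sin(theta))

# Cartesian position of a node in either layout mode
layout_xy <- function(layout, id) {
  if (layout$mode == "radial")
    polar_xy(layout$coordinates[id, 1], layout$coordinates[id, 2])
  else
    layout$coordinates[id, ]
}

dist_point_segment <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((a + t * ab - p)^2))
}

# branches whose drawn parent-to-child segment passes within `radius`
# of `point` (Cartesian layout coordinates)
branches_near_point <- function(tree, layout, point, radius) {
  out <- integer(0)
  for (key in names(layout$edge_paths)) {
    id <- as.integer(key)
    p <- tree$nodes[[id]]$parent
    a <- layout_xy(layout, p)
    b <- layout_xy(layout, id)
    if (dist_point_segment(point, a, b) <= radius) out <- c(out, id)
  }
  sort(out)
}

# centripetal Catmull-Rom point between p1 and p2 (Barry-Goldman)
catmull_point <- function(p0, p1, p2, p3, t) {
  knot <- function(ti, pa, pb) ti + sqrt(sqrt(sum((pb - pa)^2)) + 1e-12)
  t0 <- 0
  t1 <- knot(t0, p0, p1)
  t2 <- knot(t1, p1, p2)
  t3 <- knot(t2, p2, p3)
  u <- t1 + t * (t2 - t1)
  a1 <- (t1 - u) / (t1 - t0) * p0 + (u - t0) / (t1 - t0) * p1
  a2 <- (t2 - u) / (t2 - t1) * p1 + (u - t1) / (t2 - t1) * p2
  a3 <- (t3 - u) / (t3 - t2) * p2 + (u - t2) / (t3 - t2) * p3
  b1 <- (t2 - u) / (t2 - t0) * a1 + (u - t0) / (t2 - t0) * a2
  b2 <- (t3 - u) / (t3 - t1) * a2 + (u - t1) / (t3 - t1) * a3
  (t2 - u) / (t2 - t1) * b1 + (u - t1) / (t2 - t1) * b2
}

# closed centripetal Catmull-Rom polygon through the control points,
# `samples` sample points per segment (the control points are interpolated
# exactly, so they lie on the polygon boundary)
catmull_rom_closed <- function(pts, samples) {
  k <- nrow(pts)
  if (k < 3) return(pts)
  wrap <- function(i) ((i - 1) %% k) + 1
  out <- NULL
  for (i in seq_len(k)) {
    p0 <- pts[wrap(i - 1), ]; p1 <- pts[wrap(i), ]
    p2 <- pts[wrap(i + 1), ]; p3 <- pts[wrap(i + 2), ]
    ts <- seq(0, 1, length.out = samples + 1)[-(samples + 1)]
    seg <- t(vapply(ts, function(t) {
      if (t == 0) p1 else catmull_point(p0, p1, p2, p3, t)
    }, numeric(2)))
    out <- rbind(out, seg)
  }
  unname(out)
}

#' Boundary polygon of a collapsed clade
#'
#' Computes, in *full-layout* coordinates (the same layout parameters with
#' every collapse flag cleared), a closed polygon sketching the collapsed
#' subtree: the clade root's attachment point followed by the subtree's
#' leaf positions in envelope order, smoothed by a closed centripetal
#' Catmull-Rom spline sampled at `samples` points per segment.  Because
#' the spline interpolates its control points, every subtree leaf position
#' lies on (or inside) the polygon.
#'
#' @param tree a `ptree`
#' @param layout a `"tree_layout"` computed from `tree` (supplies mode,
#'   scale mode and size parameters)
#' @param node_id id of a collapsed node
#' @param samples spline sample points per segment (>= 1)
#' @return a closed polygon as a 2-column matrix of vertices
#' @export
collapsed_boundary <- function(tree, layout, node_id, samples = 20) {
  stop_unknown_id(tree, node_id)
  if (!tree$nodes[[node_id]]$collapsed)
    stop("node ", node_id, " is not collapsed", call. = FALSE)
  expanded <- tree
  for (i in seq_len(n_nodes(tree))) expanded$nodes[[i]]$collapsed <- FALSE
  full <- if (layout$mode == "radial")
    layout_radial(expanded, layout$scale_mode, layout$params$radius)
  else
    layout_rectangular(expanded, layout$scale_mode,
                       layout$params$leaf_spacing, layout$params$width)

  sub <- subtree_ids(tree, node_id)
  lv <- sub[vapply(sub, function(i)
    length(tree$nodes[[i]]$children) == 0, logical(1))]
  lv <- lv[!is.na(full$coordinates[lv, 1])]   # hidden leaves stay hidden
  pts <- t(vapply(lv, function(i) layout_xy(full, i), numeric(2)))
  attach_pt <- layout_xy(full, node_id)
  ord <- if (layout$mode == "radial")
    order(full$coordinates[lv, 2]) else order(pts[, 2])
  ctrl <- rbind(attach_pt, pts[ord, , drop = FALSE])
  catmull_rom_closed(unname(ctrl), max(1L, as.integer(samples)))
}

#' @export
print.tree_layout <- function(x, ...) {
  cat(sprintf("<tree_layout> %s %s, %d leaf slots\n",
              x$mode, x$scale_mode, length(x$leaf_order)))
  invisible(x)
}
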