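#' Rendering style for SVG output
#'
#' Styling is emitted as explicit attributes plus class names (no external
#' CSS), so rendered documents can be inspected by XML tooling.  When a
#' category has no entry in `category_styles` it is assigned a color from
#' a fixed palette in category order.
#'
#' @param default_stroke default edge color
#' @param default_width default edge stroke width (px)
#' @param category_styles named list: category -> `list(stroke =, width =)`
#' @param node_radius node glyph radius (px)
#' @param font_size leaf label font size (px)
#' @param collapsed_fill fill color for collapsed-clade wedges
#' @param link_stroke tanglegram link color
#' @param show_scale_bar draw a branch-length scale bar (phylogram only)
#' @return an object of class `"render_style"`
#' @export
render_style <- function(default_stroke = "#555555", default_width = 1,
                         category_styles = list(), node_radius = 1.5,
                         font_size = 8, collapsed_fill = "#cccccc",
                         link_stroke = "#999999", show_scale_bar = FALSE) {
  structure(list(default_stroke = default_stroke,
                 default_width = default_width,
                 category_styles = category_styles,
                 node_radius = node_radius, font_size = font_size,
                 collapsed_fill = collapsed_fill,
                 link_stroke = link_stroke,
                 show_scale_bar = isTRUE(show_scale_bar)),
            class = "render_style")
}

category_palette <- c("#e41a1c", "#377eb8", "#4daf4a", "#984ea3",
                      "#ff7f00", "#a65628", "#f781bf", "#999999")

category_style_for <- function(style, categories, category) {
  cs <- style$category_styles[[category]]
  if (!is.null(cs))
    return(list(stroke = cs$stroke %||% style$default_stroke,
                width = cs$width %||% style$default_width))
  i <- match(category, categories)
  list(stroke = category_palette[((i - 1) %% length(category_palette)) + 1],
       width = style$default_width)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

fmt <- function(x) sprintf("%.4f", x)

# deterministic affine map from layout units to pixel space
pixel_transform <- function(extents, target = 480, margin = 20) {
  w <- max(extents["xmax"] - extents["xmin"], 1e-9)
  h <- max(extents["ymax"] - extents["ymin"], 1e-9)
  k <- target / max(w, h)
  list(
    px = function(xy) c(k * (xy[1] - extents[["xmin"]]) + margin,
                        k * (xy[2] - extents[["ymin"]]) + margin),
    size = c(width = k * w + 2 * margin, height = k * h + 2 * margin),
    k = k)
}

svg_open <- function(size) {
  sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%s" ',
                 'height="%s" viewBox="0 0 %s %s">'),
          fmt(size["width"]), fmt(size["height"]),
          fmt(size["width"]), fmt(size["height"]))
}

branch_category <- function(tree, state, id) {
  if (!is.null(state)) {
    cats <- state$assignment[[as.character(id)]]
    if (length(cats) > 0) {
      ordered <- state$categories[state$categories %in% cats]
      return(ordered[1])
    }
    return(NA_character_)
  }
  if (length(tree$nodes[[id]]$tags) > 0) return(tree$nodes[[id]]$tags[1])
  NA_character_
}

branch_path_d <- function(layout, id, tr) {
  ep <- layout$edge_paths[[as.character(id)]]
  if (ep$type == "elbow") {
    a <- tr$px(ep$from); b <- tr$px(ep$corner); c <- tr$px(ep$to)
    sprintf("M %s %s L %s %s L %s %s",
            fmt(a[1]), fmt(a[2]), fmt(b[1]), fmt(b[2]), fmt(c[1]), fmt(c[2]))
  } else {
    r <- ep$arc[[1]]; a1 <- ep$arc[[2]]; a2 <- ep$arc[[3]]
    s <- tr$px(polar_xy(r, a1))
    e <- tr$px(polar_xy(r, a2))
    tip <- tr$px(polar_xy(ep$seg_to[1], ep$seg_to[2]))
    rp <- r * tr$k
    large <- if (abs(a2 - a1) > pi) 1 else 0
    sweep <- if (a2 > a1) 1 else 0
    sprintf("M %s %s A %s %s 0 %d %d %s %s L %s %s",
            fmt(s[1]), fmt(s[2]), fmt(rp), fmt(rp), large, sweep,
            fmt(e[1]), fmt(e[2]), fmt(tip[1]), fmt(tip[2]))
  }
}

#' Render a laid-out tree as an SVG document
#'
#' Emits exactly one `<path>` per visible non-root branch and one
#' `<polygon>` per outermost collapsed clade, plus node circles and leaf
#' labels.  A branch whose category resolves (from the selection state's
#' category order, falling back to stored branch tags) carries that
#' category's stroke/width, a `cat-<name>` class and a machine-readable
#' `data-category` attribute.  Output is byte-identical for identical
#' inputs: no timestamps, no generated ids.
#'
#' @param layout a `"tree_layout"` computed from `tree`
#' @param tree the `ptree` that produced `layout`
#' @param state optional [selection_state()] supplying branch categories
#' @param style a [render_style()]
#' @return the SVG document as a single string
#' @export
render_svg <- function(layout, tree, state = NULL, style = render_style()) {
  stopifnot(inherits(layout, "tree_layout"))
  if (layout$n_tree_nodes != n_nodes(tree))
    stop("layout/tree mismatch: layout was computed for a ",
         layout$n_tree_nodes, "-node tree", call. = FALSE)
  categories <- if (!is.null(state)) state$categories else
    sort(unique(unlist(lapply(tree$nodes, function(nd) nd$tags))))
  tr <- pixel_transform(layout$extents)
  out <- c(svg_open(tr$size))

  for (key in names(layout$collapsed_boundaries)) {
    poly <- layout$collapsed_boundaries[[key]]
    pix <- apply(poly, 1, tr$px)
    out <- c(out, sprintf(
      '<polygon class="collapsed" data-node="%s" points="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
      key,
      paste(fmt(pix[1, ]), fmt(pix[2, ]), sep = ",", collapse = " "),
      style$collapsed_fill, style$default_stroke,
      fmt(style$default_width)))
  }

  branch_ids <- sort(as.integer(names(layout$edge_paths)))
  for (id in branch_ids) {
    cat_name <- branch_category(tree, state, id)
    if (!is.na(cat_name)) {
      cs <- category_style_for(style, categories, cat_name)
      out <- c(out, sprintf(
        '<path class="branch cat-%s" data-category="%s" d="%s" fill="none" stroke="%s" stroke-width="%s"/>',
        xml_escape(cat_name), xml_escape(cat_name),
        branch_path_d(layout, id, tr), cs$stroke, fmt(cs$width)))
    } else {
      out <- c(out, sprintf(
        '<path class="branch" d="%s" fill="none" stroke="%s" stroke-width="%s"/>',
        branch_path_d(layout, id, tr), style$default_stroke,
        fmt(style$default_width)))
    }
  }

  vis <- which(!is.na(layout$coordinates[, 1]))
  for (id in vis) {
    p <- tr$px(layout_xy(layout, id))
    out <- c(out, sprintf(
      '<circle class="node" cx="%s" cy="%s" r="%s" fill="%s"/>',
      fmt(p[1]), fmt(p[2]), fmt(style$node_radius), style$default_stroke))
  }
  for (id in layout$leaf_order) {
    lab <- tree$nodes[[id]]$label
    if (nzchar(lab)) {
      p <- tr$px(layout_xy(layout, id))
      out <- c(out, sprintf(
        '<text class="leaf-label" x="%s" y="%s" font-size="%s">%s</text>',
        fmt(p[1] + 2 * style$node_radius),
        fmt(p[2] + style$font_size / 3),
        fmt(style$font_size), xml_escape(lab)))
    }
  }

  if (style$show_scale_bar && layout$scale_mode == "phylogram" &&
      layout$mode == "rectangular") {
    unit <- layout$params$width / 5
    x0 <- tr$px(c(layout$extents[["xmin"]], layout$extents[["ymax"]]))
    x1 <- tr$px(c(layout$extents[["xmin"]] + unit,
                  layout$extents[["ymax"]]))
    out <- c(out, sprintf(
      '<line class="scale-bar" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
      fmt(x0[1]), fmt(x0[2] + 10), fmt(x1[1]), fmt(x1[2] + 10),
      style$default_stroke, fmt(style$default_width)))
  }

  paste(c(out, "</svg>"), collapse = "\n")
}

#' Render a tanglegram as an SVG document
#'
#' The left tree is laid out left-to-right, the right tree mirrored
#' right-to-left, both as cladograms so matched leaves face each other
#' across the central gap; one `<line class="link">` is emitted per
#' matching pair, in matching order.  Output is deterministic.
#'
#' @param tg a [tanglegram()]
#' @param style a [render_style()]
#' @return the SVG document as a single string
#' @export
render_tanglegram_svg <- function(tg, style = render_style()) {
  stopifnot(inherits(tg, "tanglegram"))
  spacing <- 14; tree_w <- 150; gap <- 140; margin <- 20
  lay <- list(left = layout_rectangular(tg$left, "cladogram"),
              right = layout_rectangular(tg$right, "cladogram"))
  nl <- vapply(lay, function(l) length(l$leaf_order), integer(1))
  height <- (max(nl) - 1) * spacing + 2 * margin
  width <- 2 * tree_w + gap + 2 * margin

  side_px <- function(side) {
    ext <- lay[[side]]$extents
    function(xy) {
      sx <- xy[1] / max(ext[["xmax"]], 1e-9) * tree_w
      sy <- xy[2] * spacing + margin
      if (side == "left") c(margin + sx, sy) else c(width - margin - sx, sy)
    }
  }
  pxl <- side_px("left"); pxr <- side_px("right")

  out <- c(svg_open(c(width = width, height = height)))
  emit_tree <- function(side, px) {
    l <- lay[[side]]
    for (id in sort(as.integer(names(l$edge_paths)))) {
      ep <- l$edge_paths[[as.character(id)]]
      a <- px(ep$from); b <- px(ep$corner); c <- px(ep$to)
      out <<- c(out, sprintf(
        '<path class="branch %s" d="M %s %s L %s %s L %s %s" fill="none" stroke="%s" stroke-width="%s"/>',
        side, fmt(a[1]), fmt(a[2]), fmt(b[1]), fmt(b[2]),
        fmt(c[1]), fmt(c[2]), style$default_stroke,
        fmt(style$default_width)))
    }
  }
  emit_tree("left", pxl)
  emit_tree("right", pxr)

  for (i in seq_len(nrow(tg$links))) {
    a <- pxl(lay$left$coordinates[tg$links[i, 1], ])
    b <- pxr(lay$right$coordinates[tg$links[i, 2], ])
    out <- c(out, sprintf(
      '<line class="link" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
      fmt(a[1]), fmt(a[2]), fmt(b[1]), fmt(b[2]),
      style$link_stroke, fmt(style$default_width)))
  }
  for (side in c("left", "right")) {
    px <- if (side == "left") pxl else pxr
    l <- lay[[side]]
    tree <- tg[[side]]
    for (id in l$leaf_order) {
      lab <- tree$nodes[[id]]$label
      if (nzchar(lab)) {
        p <- px(l$coordinates[id, ])
        anchor <- if (side == "left") "start" else "end"
        dx <- if (side == "left") 3 else -3
        out <- c(out, sprintf(
          '<text class="leaf-label %s" x="%s" y="%s" font-size="%s" text-anchor="%s">%s</text>',
          side, fmt(p[1] + dx), fmt(p[2] + style$font_size / 3),
          fmt(style$font_size), anchor, xml_escape(lab)))
      }
    }
  }
  paste(c(out, "</svg>"), collapse = "\n")
}
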