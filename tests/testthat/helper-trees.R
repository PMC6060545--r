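# shared fixtures and small geometric oracles for the suite

# a deterministic corpus of Yule trees spanning small to medium sizes
yule_corpus <- function(n_trees, min_leaves = 4, max_leaves = 64,
                        seed_base = 1000) {
  lapply(seq_len(n_trees), function(i) {
    n <- min_leaves + (i * 7) %% (max_leaves - min_leaves + 1)
    generate_yule_tree(n, seed_base + i)
  })
}

# leaf counts via an independent route: count label occurrences in the
# depth-first leaf list of each subtree
leaf_count_oracle <- function(tree, node_id) {
  ids <- subtree_ids(tree, node_id)
  sum(vapply(ids, function(i) length(tree$nodes[[i]]$children) == 0,
             logical(1)))
}

# trees are equal as annotated structures: topology (child order), labels,
# tags, and branch lengths within tol
expect_same_tree <- function(a, b, tol = 1e-6) {
  expect_equal(n_nodes(a), n_nodes(b))
  walk <- function(ia, ib) {
    na <- a$nodes[[ia]]; nb <- b$nodes[[ib]]
    expect_identical(na$label, nb$label)
    expect_setequal(na$tags, nb$tags)
    if (is.na(na$branch_length) || is.na(nb$branch_length)) {
      expect_identical(is.na(na$branch_length), is.na(nb$branch_length))
    } else {
      # precision is digits after the decimal point -> absolute tolerance
      expect_lt(abs(na$branch_length - nb$branch_length), tol)
    }
    expect_equal(length(na$children), length(nb$children))
    for (k in seq_along(na$children)) walk(na$children[k], nb$children[k])
  }
  walk(a$root, b$root)
  invisible(TRUE)
}

# proper intersection of open segments (shared endpoints do not count)
segments_cross <- function(p1, p2, p3, p4) {
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- orient(p1, p2, p3); o2 <- orient(p1, p2, p4)
  o3 <- orient(p3, p4, p1); o4 <- orient(p3, p4, p2)
  o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
}

# count pairwise geometric crossings among <line> elements of class "link"
svg_link_crossings <- function(svg) {
  doc <- xml2::read_xml(svg)
  lines <- xml2::xml_find_all(doc, "//*[local-name()='line'][@class='link']")
  segs <- lapply(lines, function(l) {
    as.numeric(c(xml2::xml_attr(l, "x1"), xml2::xml_attr(l, "y1"),
                 xml2::xml_attr(l, "x2"), xml2::xml_attr(l, "y2")))
  })
  n <- length(segs); total <- 0
  if (n < 2) return(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- segs[[i]]; b <- segs[[j]]
    if (segments_cross(a[1:2], a[3:4], b[1:2], b[3:4])) total <- total + 1
  }
  total
}

count_matches <- function(pattern, text) {
  m <- gregexpr(pattern, text, fixed = TRUE)[[1]]
  if (length(m) == 1 && m == -1) 0L else length(m)
}

# polygon area by the shoelace formula
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
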