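#' Read the first phylogeny from a minimal PhyloXML document
#'
#' Reads clade nesting, clade `name`, and `branch_length` given either as
#' a nested element or as a `branch_length` attribute.  Unsupported
#' elements (confidence, taxonomy, ...) are ignored.  Only the first
#' `phylogeny` element of the document is returned.  Namespaces are
#' handled by matching on local element names.
#'
#' @param text PhyloXML document as a string
#' @return a `ptree`
#' @export
parse_phyloxml <- function(text) {
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) stop("phyloxml: XML parse failure: ",
                                           conditionMessage(e), call. = FALSE))
  phy <- xml2::xml_find_first(doc, ".//*[local-name()='phylogeny']")
  if (inherits(phy, "xml_missing"))
    stop("phyloxml: no phylogeny element", call. = FALSE)
  top <- xml2::xml_find_first(phy, "./*[local-name()='clade']")
  if (inherits(top, "xml_missing"))
    stop("phyloxml: phylogeny has no clade", call. = FALSE)

  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  build <- function(clade, parent) {
    id <- length(env$nodes) + 1L
    env$nodes[[id]] <- new_tree_node(id, parent = parent)
    nm <- xml2::xml_find_first(clade, "./*[local-name()='name']")
    if (!inherits(nm, "xml_missing"))
      env$nodes[[id]]$label <- xml2::xml_text(nm)
    bl <- xml2::xml_attr(clade, "branch_length")
    if (is.na(bl)) {
      ble <- xml2::xml_find_first(clade, "./*[local-name()='branch_length']")
      if (!inherits(ble, "xml_missing")) bl <- xml2::xml_text(ble)
    }
    if (!is.na(bl)) env$nodes[[id]]$branch_length <- as.numeric(bl)
    for (sub in xml2::xml_find_all(clade, "./*[local-name()='clade']")) {
      child <- build(sub, id)
      env$nodes[[id]]$children <- c(env$nodes[[id]]$children, child)
    }
    id
  }
  root <- build(top, NA_integer_)
  name <- xml2::xml_find_first(phy, "./*[local-name()='name']")
  validate_tree(new_tree(env$nodes, root,
                         if (inherits(name, "xml_missing")) "" else
                           xml2::xml_text(name)))
}

#' Read the first tree from a minimal NeXML document
#'
#' Reconstructs the rooted tree from the `node`/`edge` records of the first
#' `tree` element (`edge` `source` = parent, `target` = child); an edge's
#' `length` attribute becomes the child's branch length.  Leaf names come
#' from the referenced `otu` label when present, falling back to the node's
#' own `label` attribute.  Edge lists that do not form a single rooted tree
#' (multiple roots, cycles, disconnection) raise `"not-a-tree"`.
#'
#' @param text NeXML document as a string
#' @return a `ptree`
#' @export
parse_nexml <- function(text) {
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) stop("nexml: XML parse failure: ",
                                           conditionMessage(e), call. = FALSE))
  tr <- xml2::xml_find_first(doc, ".//*[local-name()='tree']")
  if (inherits(tr, "xml_missing"))
    stop("nexml: no tree element", call. = FALSE)

  otu_labels <- list()
  for (otu in xml2::xml_find_all(doc, ".//*[local-name()='otu']")) {
    oid <- xml2::xml_attr(otu, "id")
    lab <- xml2::xml_attr(otu, "label")
    if (!is.na(oid)) otu_labels[[oid]] <- if (is.na(lab)) "" else lab
  }

  xnodes <- xml2::xml_find_all(tr, "./*[local-name()='node']")
  xedges <- xml2::xml_find_all(tr, "./*[local-name()='edge']")
  if (length(xnodes) == 0) stop("nexml: tree has no nodes", call. = FALSE)

  xml_ids <- xml2::xml_attr(xnodes, "id")
  idx <- seq_along(xml_ids)
  names(idx) <- xml_ids
  nodes <- vector("list", length(xml_ids))
  for (i in idx) {
    nodes[[i]] <- new_tree_node(i)
    lab <- xml2::xml_attr(xnodes[[i]], "label")
    otu <- xml2::xml_attr(xnodes[[i]], "otu")
    if (!is.na(otu) && !is.null(otu_labels[[otu]]))
      nodes[[i]]$label <- otu_labels[[otu]]
    else if (!is.na(lab))
      nodes[[i]]$label <- lab
  }
  for (e in xedges) {
    src <- xml2::xml_attr(e, "source")
    tgt <- xml2::xml_attr(e, "target")
    if (is.na(src) || is.na(tgt) ||
        is.na(idx[src]) || is.na(idx[tgt]))
      stop("not-a-tree: edge references unknown node", call. = FALSE)
    ci <- idx[[tgt]]; pi <- idx[[src]]
    if (!is.na(nodes[[ci]]$parent))
      stop("not-a-tree: node has two parents", call. = FALSE)
    nodes[[ci]]$parent <- pi
    nodes[[pi]]$children <- c(nodes[[pi]]$children, ci)
    len <- xml2::xml_attr(e, "length")
    if (!is.na(len)) nodes[[ci]]$branch_length <- as.numeric(len)
  }
  roots <- which(vapply(nodes, function(nd) is.na(nd$parent), logical(1)))
  if (length(roots) != 1)
    stop("not-a-tree: found ", length(roots), " root nodes", call. = FALSE)
  tree <- new_tree(nodes, roots)
  reach <- tryCatch(subtree_ids(tree, roots),
                    error = function(e) integer(0))
  if (length(reach) != length(nodes) || anyDuplicated(reach))
    stop("not-a-tree: edges contain a cycle or disconnected component",
         call. = FALSE)
  validate_tree(tree)
}
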