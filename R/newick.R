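#' Newick dialect descriptor
#'
#' Three dialects are understood:
#' * `"plain"` — standard Newick; `{...}` / `[...]` blocks are errors
#'   unless `strip_unknown_comments` is set, in which case they are
#'   discarded.
#' * `"hyphy_tags"` — HyPhy-style branch annotation: a `{TAG}` block
#'   immediately after a node's label and/or after its `:length` attaches
#'   the category `TAG` to that node's subtending branch.
#' * `"beast_comments"` — BEAST-style `[&key=value,...]` blocks after
#'   labels or lengths, preserved verbatim as the node's `metadata` list
#'   (values are kept as strings, not interpreted).
#'
#' @param name one of `"plain"`, `"hyphy_tags"`, `"beast_comments"`
#' @param strip_unknown_comments discard bracketed blocks the dialect does
#'   not interpret instead of raising an error
#' @return an object of class `"newick_dialect"`
#' @export
newick_dialect <- function(name = c("plain", "hyphy_tags", "beast_comments"),
                           strip_unknown_comments = FALSE) {
  name <- match.arg(name)
  structure(list(name = name,
                 strip_unknown_comments = isTRUE(strip_unknown_comments)),
            class = "newick_dialect")
}

as_dialect <- function(d) {
  if (inherits(d, "newick_dialect")) return(d)
  if (is.character(d) && length(d) == 1) return(newick_dialect(d))
  stop("not a newick dialect", call. = FALSE)
}

#' Parse a Newick string into a tree
#'
#' A single Newick statement terminated by `";"`.  Child order, labels,
#' branch lengths, quoted labels (single-quote doubling un-escaped) and —
#' per dialect — branch tags and `[&...]` metadata are preserved.
#' Underscores in unquoted labels are kept verbatim (no underscore-to-space
#' translation).  Numbers accept decimal and exponent notation.  Syntax
#' errors report the 1-based character offset.
#'
#' @param text Newick string
#' @param dialect a [newick_dialect()] or its name
#' @return a `ptree`
#' @examples
#' t <- parse_newick("(A:0.1,B:0.2)R;")
#' n_nodes(t)  # 3
#' a <- parse_newick("(A{TEST}:0.1,B{REFERENCE}:0.2);", "hyphy_tags")
#' a$nodes[[node_by_label(a, "A")]]$tags  # "TEST"
#' @export
parse_newick <- function(text, dialect = newick_dialect("plain")) {
  dialect <- as_dialect(dialect)
  if (length(text) != 1 || !is.character(text))
    stop("text must be a single string", call. = FALSE)
  s <- strsplit(text, "", fixed = TRUE)[[1]]
  env <- new.env(parent = emptyenv())
  env$pos <- 1L
  env$nodes <- list()

  ws_chars <- c(" ", "\t", "\r", "\n")
  meta_chars <- c("(", ")", ",", ";", ":", "{", "}", "[", "]")

  fail <- function(msg) stop(sprintf("newick parse error at char %d: %s",
                                     env$pos, msg), call. = FALSE)
  peek <- function() if (env$pos <= length(s)) s[env$pos] else NA_character_
  advance <- function() env$pos <- env$pos + 1L
  skip_ws <- function() {
    while (!is.na(peek()) && peek() %in% ws_chars) advance()
  }
  new_node <- function(parent) {
    id <- length(env$nodes) + 1L
    env$nodes[[id]] <- new_tree_node(id, parent = parent)
    id
  }

  read_quoted_label <- function() {
    advance()  # opening quote
    out <- character(0)
    repeat {
      c <- peek()
      if (is.na(c)) fail("unterminated quoted label")
      if (c == "'") {
        advance()
        if (identical(peek(), "'")) { out <- c(out, "'"); advance() }
        else break
      } else { out <- c(out, c); advance() }
    }
    paste(out, collapse = "")
  }
  read_unquoted_label <- function() {
    out <- character(0)
    repeat {
      c <- peek()
      if (is.na(c) || c %in% meta_chars || c %in% ws_chars) break
      out <- c(out, c); advance()
    }
    paste(out, collapse = "")
  }
  read_until <- function(close) {
    out <- character(0)
    repeat {
      c <- peek()
      if (is.na(c)) fail(paste0("unterminated '", close, "' block"))
      if (c == close) { advance(); break }
      out <- c(out, c); advance()
    }
    paste(out, collapse = "")
  }
  read_number <- function() {
    rest <- paste(s[seq(env$pos, length(s))], collapse = "")
    m <- regmatches(rest,
      regexpr("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?", rest))
    if (length(m) == 0 || !nzchar(m)) fail("malformed branch length")
    env$pos <- env$pos + nchar(m)
    as.numeric(m)
  }
  # a `{TAG}` or `[...]` block following a label or length
  read_annotations <- function(id) {
    repeat {
      skip_ws()
      c <- peek()
      if (identical(c, "{")) {
        advance()
        tag <- read_until("}")
        if (dialect$name == "hyphy_tags") {
          env$nodes[[id]]$tags <- union(env$nodes[[id]]$tags, tag)
        } else if (!dialect$strip_unknown_comments) {
          fail(sprintf("unexpected '{%s}' under dialect '%s'",
                       tag, dialect$name))
        }
      } else if (identical(c, "[")) {
        advance()
        body <- read_until("]")
        if (dialect$name == "beast_comments" && startsWith(body, "&")) {
          kv <- strsplit(substring(body, 2), ",", fixed = TRUE)[[1]]
          for (pair in kv) {
            eq <- regexpr("=", pair, fixed = TRUE)
            if (eq > 0) {
              env$nodes[[id]]$metadata[[substr(pair, 1, eq - 1)]] <-
                substring(pair, eq + 1)
            } else if (nzchar(pair)) {
              env$nodes[[id]]$metadata[[pair]] <- TRUE
            }
          }
        } else if (!dialect$strip_unknown_comments) {
          fail(sprintf("unexpected '[%s]' under dialect '%s'",
                       body, dialect$name))
        }
      } else break
    }
  }
  # label / annotations / :length / annotations, all optional
  read_decorations <- function(id) {
    skip_ws()
    c <- peek()
    if (identical(c, "'")) {
      env$nodes[[id]]$label <- read_quoted_label()
    } else if (!is.na(c) && !(c %in% meta_chars)) {
      env$nodes[[id]]$label <- read_unquoted_label()
    }
    read_annotations(id)
    skip_ws()
    if (identical(peek(), ":")) {
      advance(); skip_ws()
      env$nodes[[id]]$branch_length <- read_number()
      read_annotations(id)
    }
  }
  read_subtree <- function(parent) {
    skip_ws()
    id <- new_node(parent)
    if (identical(peek(), "(")) {
      advance()
      repeat {
        child <- read_subtree(id)
        env$nodes[[id]]$children <- c(env$nodes[[id]]$children, child)
        skip_ws()
        c <- peek()
        if (identical(c, ",")) { advance(); next }
        if (identical(c, ")")) { advance(); break }
        fail("expected ',' or ')'")
      }
    }
    read_decorations(id)
    id
  }

  root <- read_subtree(NA_integer_)
  skip_ws()
  if (!identical(peek(), ";")) fail("expected ';'")
  advance(); skip_ws()
  if (!is.na(peek())) fail("trailing content after ';'")
  validate_tree(new_tree(env$nodes, root))
}

needs_quoting <- function(label) {
  # `]` first so the bracket expression stays POSIX-valid
  grepl("[](){},;:' \t\r\n[]", label)
}

quote_label <- function(label) {
  if (!nzchar(label)) return("")
  if (needs_quoting(label))
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  else label
}

format_length <- function(x, precision) {
  out <- sprintf("%.*f", precision, x)
  out <- sub("0+$", "", out)
  sub("\\.$", "", out)
}

#' Serialize a tree to Newick
#'
#' Child order is emitted exactly as stored.  Under `hyphy_tags`, each
#' branch carrying one category tag gets a `{tag}` block after its label;
#' a branch with more than one tag raises `"ambiguous-tag"` (serialize
#' selections through [serialize_selection()] to apply a priority), and a
#' tag containing `}` raises `"untaggable"`.  Under `beast_comments`,
#' node `metadata` is written back as `[&key=value,...]`.  Labels
#' containing Newick metacharacters are automatically single-quoted.
#' Absent branch lengths are omitted, not written as 0.
#'
#' @param tree a `ptree`
#' @param dialect a [newick_dialect()] or its name
#' @param precision digits after the decimal point for branch lengths
#'   (trailing zeros trimmed)
#' @return a Newick string terminated by `";"`
#' @export
write_newick <- function(tree, dialect = newick_dialect("plain"),
                         precision = 6) {
  dialect <- as_dialect(dialect)
  wr <- function(id) {
    nd <- tree$nodes[[id]]
    inner <- if (length(nd$children) > 0)
      paste0("(", paste(vapply(nd$children, wr, character(1)),
                        collapse = ","), ")")
    else ""
    tagpart <- ""
    if (dialect$name == "hyphy_tags" && length(nd$tags) > 0) {
      if (length(nd$tags) > 1)
        stop("ambiguous-tag: node ", id, " carries ", length(nd$tags),
             " tags; serialize with a category priority", call. = FALSE)
      if (grepl("}", nd$tags, fixed = TRUE))
        stop("untaggable: tag contains '}'", call. = FALSE)
      tagpart <- paste0("{", nd$tags, "}")
    }
    metapart <- ""
    if (dialect$name == "beast_comments" && length(nd$metadata) > 0) {
      kv <- vapply(names(nd$metadata), function(k) {
        v <- nd$metadata[[k]]
        if (isTRUE(v)) k else paste0(k, "=", v)
      }, character(1))
      metapart <- paste0("[&", paste(kv, collapse = ","), "]")
    }
    lenpart <- if (!is.na(nd$branch_length))
      paste0(":", format_length(nd$branch_length, precision)) else ""
    paste0(inner, quote_label(nd$label), tagpart, metapart, lenpart)
  }
  paste0(wr(tree$root), ";")
}

#' Read a tree from a file, auto-detecting the format
#'
#' Content whose first non-whitespace character is `<` is parsed as XML and
#' dispatched on the root element (`phyloxml` or `nexml`); anything else is
#' parsed as Newick with the supplied dialect.
#'
#' @param path file path
#' @param dialect Newick dialect used when the file is Newick
#' @return a `ptree`
#' @export
read_tree <- function(path, dialect = newick_dialect("plain")) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  parse_tree_text(text, dialect)
}

parse_tree_text <- function(text, dialect = newick_dialect("plain")) {
  trimmed <- sub("^[ \t\r\n]+", "", text)
  if (startsWith(trimmed, "<")) {
    doc <- xml2::read_xml(text)
    root <- xml2::xml_name(doc)
    if (identical(root, "phyloxml")) return(parse_phyloxml(text))
    if (identical(root, "nexml")) return(parse_nexml(text))
    stop("unrecognized XML root element: ", root, call. = FALSE)
  }
  parse_newick(text, dialect)
}
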