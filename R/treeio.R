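# Readers and writers.
#
# Three formats:
#   * enewick       -- extended Newick for networks; reticulations carry
#                      "#Hk" tags, a parent referencing the same tag twice
#                      encodes parallel arcs. No branch lengths.
#   * mul_newick    -- plain Newick with repeated leaf labels (MUL-trees).
#   * json_edgelist -- lossless JSON dialect (vertex list, arc list with
#                      keys, root, label map); the normative interchange
#                      format, and the only one able to carry pseudo trees.
# Writers order children canonically, so isomorphic objects serialise to
# identical text.

#' Read a network from extended Newick
#'
#' Parses the minimal extended-Newick dialect used by this package: internal
#' names are optional, hybrid (reticulation) vertices are written as `#Hk`
#' tags and merged by tag, and the same parent referencing `#Hk` twice
#' encodes two parallel arcs. Branch lengths are rejected.
#'
#' @param text A single character string, e.g. `"((a,(c)#H1),((#H1),b));"`.
#' @return A `phydag`; its validation report (as an X-network) is attached as
#'   attribute `"validation"`.
#' @export
read_enewick <- function(text) {
  text <- trimws(text)
  if (grepl(":", text, fixed = TRUE))
    stop("branch lengths are not supported in this dialect (found ':')")
  if (!nzchar(text)) stop("empty input")
  src <- sub(";\\s*$", "", text)
  pos <- 1L
  n <- nchar(src)
  peek <- function() if (pos <= n) substr(src, pos, pos) else ""
  fail <- function(msg) stop(sprintf("parse error at position %d: %s", pos, msg))

  counter <- new.env(parent = emptyenv()); counter$i <- 0L
  nodes <- list()   # each: list(id, name, tag, children = chr vector of ids)

  parse_name <- function() {
    rest <- substr(src, pos, n)
    m <- regmatches(rest, regexpr("^[^(),;#]+", rest))
    if (!length(m) || !nzchar(m)) return("")
    pos <<- pos + nchar(m)
    trimws(m)
  }
  parse_tag <- function() {
    rest <- substr(src, pos, n)
    m <- regmatches(rest, regexpr("^#H?[0-9]+", rest))
    if (!length(m) || !nzchar(m)) fail("malformed hybrid tag")
    pos <<- pos + nchar(m)
    sub("^#H?", "", m)
  }
  parse_node <- function() {
    children <- character(0)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        children <- c(children, parse_node())
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        fail("expected ',' or ')'")
      }
    }
    name <- parse_name()
    tag <- if (peek() == "#") parse_tag() else ""
    counter$i <- counter$i + 1L
    id <- paste0(".o", counter$i)
    nodes[[id]] <<- list(id = id, name = name, tag = tag, children = children)
    id
  }
  root_occ <- parse_node()
  if (pos <= n) fail("trailing characters")

  # Merge occurrences sharing a hybrid tag into one vertex; every occurrence
  # contributes its children and its incoming arc (a parent that references
  # the same tag twice therefore yields two parallel arcs).
  rep_of <- stats::setNames(names(nodes), names(nodes))
  for (nd in nodes)
    if (nzchar(nd$tag)) rep_of[[nd$id]] <- paste0(".h", nd$tag)
  vertices <- unique(unname(rep_of))
  tails <- character(0); heads <- character(0)
  for (nd in nodes)
    for (ch in nd$children) {
      tails <- c(tails, rep_of[[nd$id]])
      heads <- c(heads, rep_of[[ch]])
    }
  pair <- paste(tails, heads, sep = "\r")
  key <- if (length(pair))
    as.integer(stats::ave(seq_along(pair), pair, FUN = seq_along) - 1L)
  else integer(0)

  # A merged vertex is a leaf when no occurrence gave it children; its label
  # is the (unique) name attached to any of its occurrences.
  labels <- character(0)
  for (nd in nodes) {
    v <- rep_of[[nd$id]]
    if (!v %in% tails) {
      if (nzchar(nd$name)) {
        if (v %in% names(labels) && labels[[v]] != nd$name)
          stop("conflicting labels for one hybrid leaf: ",
               labels[[v]], " vs ", nd$name)
        labels[v] <- nd$name
      }
    }
  }
  leaf_ids <- setdiff(vertices, unique(tails))
  miss <- setdiff(leaf_ids, names(labels))
  if (length(miss)) stop("leaf without a label in input")

  # Cosmetic: rename vertices to their given names (leaf labels, internal
  # names) when that leaves ids unique.
  ren <- stats::setNames(vertices, vertices)
  for (nd in nodes) {
    v <- rep_of[[nd$id]]
    if (nzchar(nd$name) && v %in% tails && ren[[v]] == v) ren[v] <- nd$name
  }
  for (v in names(labels)) ren[v] <- labels[[v]]
  if (anyDuplicated(unname(ren[vertices]))) ren[] <- vertices
  g <- phydag(unname(ren[vertices]),
              data.frame(tail = unname(ren[tails]), head = unname(ren[heads]),
                         key = key, stringsAsFactors = FALSE),
              unname(ren[[rep_of[[root_occ]]]]),
              stats::setNames(unname(labels), unname(ren[names(labels)])))
  # wrapper vertices around a bare hybrid reference, e.g. "((#H1)q,b)", come
  # out with in- and out-degree one; suppress them
  g <- suppress_degree_two(g)
  attr(g, "validation") <- validate_graph(g, "x_network")
  g
}

#' Read a MUL-tree from Newick with repeated labels
#'
#' @param text A Newick string such as `"((a,c),(b,c));"`; leaf labels may
#'   repeat. Branch lengths are rejected.
#' @return A `phydag` tree; its validation report (as a MUL-tree) is attached
#'   as attribute `"validation"`.
#' @export
read_mul_newick <- function(text) {
  text <- trimws(text)
  if (grepl(":", text, fixed = TRUE))
    stop("branch lengths are not supported in this dialect (found ':')")
  src <- sub(";\\s*$", "", text)
  pos <- 1L; n <- nchar(src)
  peek <- function() if (pos <= n) substr(src, pos, pos) else ""
  fail <- function(msg) stop(sprintf("parse error at position %d: %s", pos, msg))
  counter <- new.env(parent = emptyenv()); counter$i <- 0L
  verts <- character(0); tails <- character(0); heads <- character(0)
  labels <- character(0)
  parse_node <- function() {
    counter$i <- counter$i + 1L
    id <- paste0("t", counter$i)
    verts <<- c(verts, id)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        ch <- parse_node()
        tails <<- c(tails, id); heads <<- c(heads, ch)
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        fail("expected ',' or ')'")
      }
      # optional internal name, ignored
      rest <- substr(src, pos, n)
      m <- regmatches(rest, regexpr("^[^(),;]+", rest))
      if (length(m) && nzchar(m)) pos <<- pos + nchar(m)
    } else {
      rest <- substr(src, pos, n)
      m <- regmatches(rest, regexpr("^[^(),;]+", rest))
      if (!length(m) || !nzchar(trimws(m))) fail("expected a leaf label")
      pos <<- pos + nchar(m)
      labels[id] <<- trimws(m)
    }
    id
  }
  root_id <- parse_node()
  if (pos <= n) fail("trailing characters")
  g <- phydag(verts, data.frame(tail = tails, head = heads,
                                stringsAsFactors = FALSE),
              root_id, labels)
  attr(g, "validation") <- validate_graph(g, "mul_tree")
  g
}

# ---------------------------------------------------------------------------
# Writers.

#' Write a (pseudo) MUL-tree as Newick
#'
#' Children are ordered by canonical form, so isomorphic trees produce
#' identical text. Degree-two vertices cannot be represented and raise an
#' error directing to the JSON edge-list format.
#'
#' @param t A `phydag` tree with all leaves labelled.
#' @return A single Newick string.
#' @export
write_mul_newick <- function(t) {
  adj <- graph_adj(t)
  deg2 <- setdiff(names(adj$indeg)[adj$indeg == 1L & adj$outdeg == 1L], t$root)
  if (length(deg2))
    stop("tree has degree-two vertices; use write_json_edgelist() instead")
  codes <- canonical_codes(t)
  emit <- function(v) {
    kids <- adj$children[[v]]
    if (!length(kids)) return(g_label(t, v))
    kids <- kids[order(codes[kids], method = "radix")]
    paste0("(", paste(vapply(kids, emit, character(1)), collapse = ","), ")")
  }
  paste0(emit(t$root), ";")
}

#' Write a network as extended Newick
#'
#' Reticulations are tagged `#Hk` in canonical discovery order; the full
#' subtree is emitted at the first encounter and later encounters emit only
#' the tag. A parent holding two parallel arcs to a reticulation repeats the
#' tag. Children are ordered canonically so isomorphic networks produce
#' identical text.
#'
#' @param n A `phydag` network (parallel arcs allowed). Unlabelled leaves
#'   cannot be represented and raise an error.
#' @return A single extended-Newick string.
#' @export
write_enewick <- function(n) {
  adj <- graph_adj(n)
  leaves <- names(adj$outdeg)[adj$outdeg == 0L]
  if (!all(leaves %in% names(n$labels)))
    stop("unlabelled leaves; use write_json_edgelist() instead")
  cn <- canon_network(n)
  rank <- stats::setNames(seq_along(cn$order), cn$order)
  rets <- names(adj$indeg)[adj$indeg >= 2L]
  state <- new.env(parent = emptyenv())
  state$tag <- stats::setNames(integer(0), character(0))
  state$next_tag <- 0L
  state$defined <- character(0)
  emit <- function(v) {
    is_ret <- v %in% rets
    tag <- ""
    if (is_ret) {
      if (!v %in% names(state$tag)) {
        state$next_tag <- state$next_tag + 1L
        state$tag[v] <- state$next_tag
      }
      tag <- paste0("#H", state$tag[[v]])
      if (v %in% state$defined) return(tag)
      state$defined <- c(state$defined, v)
    }
    kids <- adj$children[[v]]
    if (!length(kids)) return(paste0(g_label(n, v), tag))
    kids <- kids[order(rank[kids])]
    paste0("(", paste(vapply(kids, emit, character(1)), collapse = ","), ")", tag)
  }
  paste0(emit(n$root), ";")
}

#' Write any graph as a lossless JSON edge list
#'
#' The normative interchange format: explicit vertex list, arc list with
#' keys, root id and leaf-label map. Vertices are renamed positionally along
#' a canonical order, so `write_json_edgelist(x) == write_json_edgelist(y)`
#' exactly when `x` and `y` are isomorphic.
#'
#' @param g A `phydag` (network, tree or pseudo tree).
#' @return A single JSON string.
#' @export
write_json_edgelist <- function(g) {
  cn <- canon_network(g)
  ren <- stats::setNames(paste0("n", seq_along(cn$order)), cn$order)
  arcs <- data.frame(tail = unname(ren[g$arcs$tail]),
                     head = unname(ren[g$arcs$head]),
                     key = g$arcs$key, stringsAsFactors = FALSE)
  arcs <- arcs[order(arcs$tail, arcs$head, arcs$key, method = "radix"), ,
               drop = FALSE]
  labs <- g$labels
  obj <- list(vertices = unname(sort(ren[g$vertices], method = "radix")),
              arcs = lapply(seq_len(nrow(arcs)), function(i)
                list(tail = arcs$tail[[i]], head = arcs$head[[i]],
                     key = arcs$key[[i]])),
              root = unname(ren[[g$root]]),
              labels = as.list(stats::setNames(unname(labs),
                                               unname(ren[names(labs)]))))
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE))
}

#' Read a graph from the JSON edge-list format
#'
#' @param text JSON produced by [write_json_edgelist()] (or equivalent).
#' @return A `phydag`.
#' @export
read_json_edgelist <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  arcs <- if (length(obj$arcs))
    data.frame(tail = vapply(obj$arcs, `[[`, character(1), "tail"),
               head = vapply(obj$arcs, `[[`, character(1), "head"),
               key = vapply(obj$arcs, function(a)
                 as.integer(a$key %||% 0L), integer(1)),
               stringsAsFactors = FALSE)
  else NULL
  labels <- if (length(obj$labels))
    stats::setNames(vapply(obj$labels, as.character, character(1)),
                    names(obj$labels))
  else character(0)
  phydag(unlist(obj$vertices), arcs, obj$root, labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write in a named format
#'
#' Convenience dispatchers over the three serialisation formats.
#'
#' @param text Serialised text.
#' @param g A `phydag`.
#' @param format One of `"enewick"`, `"mul_newick"`, `"json_edgelist"`.
#' @return `read_graph()` a `phydag`; `write_graph()` a character string.
#' @export
read_graph <- function(text, format = c("enewick", "mul_newick",
                                        "json_edgelist")) {
  format <- match.arg(format)
  switch(format,
         enewick = read_enewick(text),
         mul_newick = read_mul_newick(text),
         json_edgelist = read_json_edgelist(text))
}

#' @rdname read_graph
#' @export
write_graph <- function(g, format = c("enewick", "mul_newick",
                                      "json_edgelist")) {
  format <- match.arg(format)
  switch(format,
         enewick = write_enewick(g),
         mul_newick = write_mul_newick(g),
         json_edgelist = write_json_edgelist(g))
}
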