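# Core data model: rooted DAGs with (possibly parallel) arcs, leaf labels,
# structural predicates, degree-two suppression, subtree/restriction helpers.
#
# A graph is a plain list (class "phydag") with fields
#   vertices : character vector of vertex ids (unique)
#   arcs     : data.frame(tail, head, key) -- key disambiguates parallel arcs
#   root     : id of the root vertex
#   labels   : named character vector, names are leaf ids, values are labels
# Vertex ids are opaque and stable under every operation that keeps the vertex.

#' Construct a rooted DAG
#'
#' Builds the basic container used throughout the package for X-networks,
#' phylogenetic networks and (pseudo) MUL-trees. No structural validation is
#' performed beyond field hygiene; use [validate_graph()] to check the
#' invariants of a particular kind.
#'
#' @param vertices Character vector of vertex ids (must be unique).
#' @param arcs Data frame with character columns `tail`, `head` and an
#'   optional integer column `key` (defaults to 0; used to tell parallel arcs
#'   apart, so `(tail, head, key)` must be unique).
#' @param root Id of the root vertex.
#' @param labels Named character vector mapping leaf ids to labels. May be
#'   empty for graphs whose leaves are not labelled yet.
#' @return An object of class `phydag`.
#' @examples
#' g <- phydag(c("r", "a", "b"),
#'             data.frame(tail = c("r", "r"), head = c("a", "b")),
#'             root = "r", labels = c(a = "a", b = "b"))
#' @export
phydag <- function(vertices, arcs, root, labels = character()) {
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices)) stop("duplicate vertex ids")
  if (is.null(arcs) || nrow(arcs) == 0) {
    arcs <- data.frame(tail = character(), head = character(),
                       key = integer(), stringsAsFactors = FALSE)
  } else {
    arcs <- data.frame(tail = as.character(arcs$tail),
                       head = as.character(arcs$head),
                       key = if ("key" %in% names(arcs)) as.integer(arcs$key)
                             else integer(nrow(arcs)),
                       stringsAsFactors = FALSE)
  }
  if (anyDuplicated(arcs[c("tail", "head", "key")]))
    stop("duplicate (tail, head, key) arc triples")
  bad <- setdiff(c(arcs$tail, arcs$head), vertices)
  if (length(bad)) stop("arcs reference unknown vertices: ",
                        paste(bad, collapse = ", "))
  if (!root %in% vertices) stop("root is not a vertex")
  labels <- labels[intersect(names(labels), vertices)]
  structure(list(vertices = vertices, arcs = arcs,
                 root = as.character(root),
                 labels = if (length(labels)) labels else
                   stats::setNames(character(), character())),
            class = "phydag")
}

#' @export
print.phydag <- function(x, ...) {
  cat(sprintf("<phydag> %d vertices, %d arcs, root '%s'\n",
              length(x$vertices), nrow(x$arcs), x$root))
  if (length(x$labels))
    cat("  leaves:", paste(sprintf("%s=%s", names(x$labels), x$labels),
                           collapse = " "), "\n")
  invisible(x)
}

# Stable string id for an arc; used by morphisms and reconciliation paths.
arc_id <- function(tail, head, key = 0L) paste(tail, head, key, sep = "|")

arc_ids <- function(g) arc_id(g$arcs$tail, g$arcs$head, g$arcs$key)

# Adjacency (children/parents with multiplicity, in arc-row order).
graph_adj <- function(g) {
  fv <- factor(g$arcs$tail, levels = g$vertices)
  fw <- factor(g$arcs$head, levels = g$vertices)
  ch <- split(g$arcs$head, fv)
  pa <- split(g$arcs$tail, fw)
  list(children = ch, parents = pa,
       outdeg = lengths(ch), indeg = lengths(pa))
}

# Topological order (root first). Returns NULL when the graph has a cycle or
# vertices unreachable from the root.
topo_order <- function(g, adj = graph_adj(g)) {
  indeg <- adj$indeg
  queue <- names(indeg)[indeg == 0L]
  if (!identical(sort(queue), sort(g$root)) && length(queue) != 1L) {
    # more than one source: still attempt ordering for diagnostics
  }
  out <- character(0)
  indeg_left <- indeg
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in unique(adj$children[[v]])) {
      k <- sum(adj$children[[v]] == w)
      indeg_left[[w]] <- indeg_left[[w]] - k
      if (indeg_left[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(g$vertices)) return(NULL)
  out
}

# All vertices reachable from v (inclusive).
descendants_incl <- function(g, v, adj = graph_adj(g)) {
  seen <- structure(logical(length(g$vertices)), names = g$vertices)
  stack <- v
  while (length(stack)) {
    x <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (seen[[x]]) next
    seen[[x]] <- TRUE
    stack <- c(stack, unique(adj$children[[x]]))
  }
  names(seen)[seen]
}

#' Classify a vertex of a rooted DAG
#'
#' Classifies `v` by its in- and out-degree: the root (in-degree 0), a
#' reticulation (in-degree at least 2, out-degree 1), a leaf (out-degree 0) or
#' an internal tree vertex (in-degree 1, out-degree at least 2). Degree-two
#' vertices of pseudo MUL-trees (in-degree 1, out-degree 1) are reported as
#' `"subdivision"`.
#'
#' @param g A `phydag`.
#' @param v A vertex id of `g`.
#' @return One of `"root"`, `"reticulation"`, `"internal_tree"`, `"leaf"`,
#'   `"subdivision"`.
#' @export
vertex_class <- function(g, v) {
  if (!v %in% g$vertices) stop("vertex not in graph: ", v)
  adj <- graph_adj(g)
  indeg <- adj$indeg[[v]]; outdeg <- adj$outdeg[[v]]
  if (v == g$root || indeg == 0L) return("root")
  if (outdeg == 0L) return("leaf")
  if (indeg >= 2L && outdeg == 1L) return("reticulation")
  if (indeg == 1L && outdeg >= 2L) return("internal_tree")
  "subdivision"
}

#' Validate a graph against the invariants of a structural kind
#'
#' Checks the defining conditions of the requested kind and reports every
#' violation instead of raising an error. The kinds are: `x_network` (single
#' root of out-degree at least 2, every non-root vertex a reticulation or a
#' tree vertex, no degree-two vertices, leaves labelled bijectively by a label
#' set of size at least two, parallel arcs allowed), `phylo_network`
#' (an X-network without parallel arcs), `pseudo_mul_tree` (a rooted tree with
#' every leaf labelled, repeated labels allowed, degree-two vertices allowed)
#' and `mul_tree` (a pseudo MUL-tree without degree-two vertices).
#'
#' @param g A `phydag`.
#' @param kind One of `"x_network"`, `"phylo_network"`, `"mul_tree"`,
#'   `"pseudo_mul_tree"`.
#' @return A list with `ok` (logical) and `violations` (character vector, one
#'   message per violated invariant, naming offending vertices or arcs).
#' @export
validate_graph <- function(g, kind = c("x_network", "phylo_network",
                                       "mul_tree", "pseudo_mul_tree")) {
  kind <- match.arg(kind)
  bad <- character(0)
  adj <- graph_adj(g)
  indeg <- adj$indeg; outdeg <- adj$outdeg

  sources <- names(indeg)[indeg == 0L]
  if (length(sources) != 1L)
    bad <- c(bad, paste0("expected exactly one in-degree-0 vertex, found: ",
                         paste(sources, collapse = ", ")))
  if (!g$root %in% sources)
    bad <- c(bad, sprintf("declared root '%s' has in-degree %d",
                          g$root, indeg[[g$root]]))
  ord <- topo_order(g, adj)
  if (is.null(ord)) bad <- c(bad, "graph contains a directed cycle")
  reach <- descendants_incl(g, g$root, adj)
  un <- setdiff(g$vertices, reach)
  if (length(un))
    bad <- c(bad, paste0("vertices unreachable from the root: ",
                         paste(un, collapse = ", ")))

  leaves <- names(outdeg)[outdeg == 0L]
  unl <- setdiff(leaves, names(g$labels))
  deg2 <- setdiff(names(indeg)[indeg == 1L & outdeg == 1L], g$root)

  if (kind %in% c("x_network", "phylo_network")) {
    if (outdeg[[g$root]] < 2L)
      bad <- c(bad, sprintf("root outdegree < 2 (root '%s' has outdegree %d)",
                            g$root, outdeg[[g$root]]))
    for (v in setdiff(g$vertices, g$root)) {
      cl <- if (outdeg[[v]] == 0L && indeg[[v]] == 1L) "leaf"
            else if (indeg[[v]] >= 2L && outdeg[[v]] == 1L) "reticulation"
            else if (indeg[[v]] == 1L && outdeg[[v]] >= 2L) "tree"
            else NA_character_
      if (is.na(cl))
        bad <- c(bad, sprintf(
          "vertex '%s' (indeg %d, outdeg %d) is neither a reticulation nor a tree vertex",
          v, indeg[[v]], outdeg[[v]]))
    }
    if (length(unl))
      bad <- c(bad, paste0("unlabelled leaves: ", paste(unl, collapse = ", ")))
    labs <- g$labels[intersect(names(g$labels), leaves)]
    if (anyDuplicated(labs))
      bad <- c(bad, paste0("label used by more than one leaf: ",
                           paste(unique(labs[duplicated(labs)]), collapse = ", ")))
    if (length(unique(labs)) < 2L)
      bad <- c(bad, "label set X has fewer than two elements")
    if (kind == "phylo_network" &&
        anyDuplicated(g$arcs[c("tail", "head")]) > 0L) {
      dup <- g$arcs[duplicated(g$arcs[c("tail", "head")]), , drop = FALSE]
      bad <- c(bad, paste0("parallel arcs: ",
                           paste(unique(arc_id(dup$tail, dup$head, dup$key)),
                                 collapse = ", ")))
    }
  } else {
    nonroot <- setdiff(g$vertices, g$root)
    multi <- nonroot[indeg[nonroot] != 1L]
    if (length(multi))
      bad <- c(bad, paste0("not a tree; vertices with indegree != 1: ",
                           paste(multi, collapse = ", ")))
    if (length(unl))
      bad <- c(bad, paste0("unlabelled leaves: ", paste(unl, collapse = ", ")))
    if (kind == "mul_tree" && length(deg2))
      bad <- c(bad, paste0("degree-two vertices: ", paste(deg2, collapse = ", ")))
  }
  list(ok = length(bad) == 0L, violations = bad)
}

#' Structural properties of an X-network
#'
#' Computes the standard property flags of a network: `binary` (every
#' reticulation has in-degree 2 and out-degree 1, every internal tree vertex
#' has out-degree 2, and the root has out-degree 2), `semi_resolved` (every
#' internal tree vertex has out-degree 2), `compressed` (the child of every
#' reticulation is a tree vertex), `tree_child` (every non-leaf vertex has at
#' least one child that is a tree vertex), `tree_sibling` (every reticulation
#' has a sibling, via some shared parent, that is a tree vertex),
#' `has_parallel_arcs`, and `is_tree` (no reticulations and no parallel arcs).
#'
#' @param n A `phydag` that validates as an X-network.
#' @return A named list of logical flags (class `property_report`).
#' @export
net_properties <- function(n) {
  chk <- validate_graph(n, "x_network")
  if (!chk$ok) stop("not a valid X-network: ",
                    paste(chk$violations, collapse = "; "))
  adj <- graph_adj(n)
  indeg <- adj$indeg; outdeg <- adj$outdeg
  is_leaf <- outdeg == 0L
  is_ret <- indeg >= 2L & outdeg == 1L
  is_treev <- !is_ret & names(indeg) != n$root       # leaves + internal tree
  rets <- names(indeg)[is_ret]
  internal_tree <- names(indeg)[is_treev & !is_leaf]

  binary <- all(indeg[rets] == 2L) && all(outdeg[internal_tree] == 2L) &&
    outdeg[[n$root]] == 2L
  semi <- all(outdeg[internal_tree] == 2L)
  compressed <- all(vapply(rets, function(r) {
    child <- adj$children[[r]][[1L]]
    is_treev[[child]]
  }, logical(1)))
  nonleaf <- names(outdeg)[outdeg > 0L]
  tree_child <- all(vapply(nonleaf, function(v) {
    any(is_treev[unique(adj$children[[v]])])
  }, logical(1)))
  tree_sibling <- all(vapply(rets, function(r) {
    sibs <- setdiff(unique(unlist(
      lapply(unique(adj$parents[[r]]), function(p) adj$children[[p]]))), r)
    length(sibs) > 0L && any(is_treev[sibs])
  }, logical(1)))
  par <- anyDuplicated(n$arcs[c("tail", "head")]) > 0L
  structure(list(binary = binary, semi_resolved = semi,
                 compressed = compressed, tree_child = tree_child,
                 tree_sibling = tree_sibling, has_parallel_arcs = par,
                 is_tree = length(rets) == 0L && !par),
            class = "property_report")
}

#' @export
print.property_report <- function(x, ...) {
  cat("<property_report>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, x[[nm]]))
  invisible(x)
}

#' Suppress all degree-two vertices
#'
#' Repeatedly replaces each non-root vertex with in-degree 1 and out-degree 1
#' by an arc from its parent to its child, until none remain. All other
#' vertices keep their ids, and leaf labels are untouched. Suppressing the two
#' inner vertices of a "diamond" creates parallel arcs, which receive fresh
#' keys.
#'
#' @param g A `phydag`.
#' @return A `phydag` with no degree-two vertices.
#' @export
suppress_degree_two <- function(g) {
  adj <- graph_adj(g)
  supp <- setdiff(names(adj$indeg)[adj$indeg == 1L & adj$outdeg == 1L], g$root)
  if (!length(supp)) return(g)
  child_of <- vapply(supp, function(v) adj$children[[v]][[1L]], character(1))
  resolve <- function(h) {                  # walk chains of suppressed vertices
    while (h %in% supp) h <- child_of[[h]]
    h
  }
  keep <- !(g$arcs$tail %in% supp)
  tails <- g$arcs$tail[keep]
  heads <- vapply(g$arcs$head[keep], resolve, character(1), USE.NAMES = FALSE)
  pair <- paste(tails, heads, sep = "\r")
  key <- stats::ave(seq_along(pair), pair, FUN = seq_along) - 1L
  phydag(setdiff(g$vertices, supp),
         data.frame(tail = tails, head = heads, key = as.integer(key),
                    stringsAsFactors = FALSE),
         g$root, g$labels)
}

#' Extract the subtree rooted at a vertex
#'
#' Returns `T(v)`: the connected subgraph of a (pseudo) MUL-tree containing
#' `v` after removing the incoming arc of `v`, rooted at `v` and carrying the
#' restriction of the leaf labelling.
#'
#' @param t A `phydag` that is a tree.
#' @param v A non-root vertex id of `t`.
#' @return A `phydag` rooted at `v`.
#' @export
subtree_at <- function(t, v) {
  if (v == t$root) stop("subtree_at is defined for non-root vertices only")
  induced_below(t, v)
}

# Induced subgraph on v and everything below it (no suppression).
induced_below <- function(g, v) {
  keep <- descendants_incl(g, v)
  arcs <- g$arcs[g$arcs$tail %in% keep & g$arcs$head %in% keep, , drop = FALSE]
  phydag(keep, arcs, v, g$labels[intersect(names(g$labels), keep)])
}

#' Restrict a network below a vertex
#'
#' Returns `N(u)`: the restriction of `n` to `u` and all vertices below it,
#' followed by suppression of any resulting degree-two vertices (reticulations
#' that lose all but one parent become suppressible).
#'
#' @param n A `phydag` network.
#' @param u A tree vertex or the root of `n`.
#' @return A `phydag` rooted at `u`.
#' @export
restrict_below <- function(n, u) {
  if (vertex_class(n, u) == "reticulation")
    stop("restrict_below is not defined at reticulation vertices")
  suppress_degree_two(induced_below(n, u))
}
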