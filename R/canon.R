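# Canonical forms and isomorphism tests.
#
# (Pseudo) MUL-trees get sorted-multiset codes computed bottom-up; equality of
# root codes is a complete isomorphism invariant. Networks are canonicalised
# by colour refinement with individualisation, which also yields a witness
# bijection for the isomorphism test.

#' Canonical codes of every vertex of a (pseudo) MUL-tree
#'
#' Computes, bottom-up, a canonical code for the subtree below each vertex: a
#' leaf labelled `x` gets `"L(x)"`, a degree-two (subdivision) vertex gets
#' `"D(<child>)"`, and any other vertex gets `"I(...)"` wrapping the sorted
#' multiset of its children's codes. Two non-root vertices have equal codes if
#' and only if their subtrees are isomorphic as pseudo MUL-trees (subdivision
#' patterns matter).
#'
#' @param t A `phydag` tree whose leaves are all labelled.
#' @return Named character vector of codes, one per vertex.
#' @export
canonical_codes <- function(t) {
  adj <- graph_adj(t)
  ord <- topo_order(t, adj)
  if (is.null(ord)) stop("not an acyclic rooted graph")
  codes <- structure(character(length(t$vertices)), names = t$vertices)
  for (v in rev(ord)) {
    if (adj$outdeg[[v]] == 0L) {
      lab <- g_label(t, v)
      if (is.na(lab)) stop("unlabelled leaf: ", v)
      codes[[v]] <- paste0("L(", lab, ")")
    } else if (v != t$root && adj$indeg[[v]] == 1L && adj$outdeg[[v]] == 1L) {
      codes[[v]] <- paste0("D(", codes[[adj$children[[v]][[1L]]]], ")")
    } else {
      kids <- sort(codes[adj$children[[v]]], method = "radix")
      codes[[v]] <- paste0("I(", paste(kids, collapse = ","), ")")
    }
  }
  codes
}

g_label <- function(g, v) {
  if (v %in% names(g$labels)) g$labels[[v]] else NA_character_
}

#' Canonical form of a (pseudo) MUL-tree or one of its subtrees
#'
#' @param t A `phydag` tree.
#' @param v A vertex id; defaults to the root (the code of the whole tree).
#' @return A character string; equal strings characterise isomorphic
#'   (sub)trees.
#' @export
canonical_form <- function(t, v = t$root) {
  codes <- canonical_codes(t)
  if (!v %in% names(codes)) stop("vertex not in tree: ", v)
  codes[[v]]
}

#' Isomorphism of (pseudo) MUL-trees
#'
#' Decides label-respecting digraph isomorphism by comparing root canonical
#' forms. Pseudo trees with different subdivision patterns are not isomorphic.
#'
#' @param t1,t2 `phydag` trees.
#' @return `TRUE` or `FALSE`.
#' @export
multree_isomorphic <- function(t1, t2) {
  identical(canonical_form(t1), canonical_form(t2))
}

# ---------------------------------------------------------------------------
# Network canonicalisation (colour refinement + individualisation).

# Initial colours: leaves by label, everything else by (indeg, outdeg, root?).
init_colors <- function(g, adj) {
  vapply(g$vertices, function(v) {
    lab <- g_label(g, v)
    if (adj$outdeg[[v]] == 0L && !is.na(lab)) paste0("x:", lab)
    else paste0("d:", adj$indeg[[v]], ",", adj$outdeg[[v]],
                if (v == g$root) ",r" else "")
  }, character(1))
}

# One refinement pass over colour vector `col` (named by vertex).
refine_colors <- function(g, adj, col) {
  repeat {
    sig <- vapply(g$vertices, function(v) {
      paste(col[[v]],
            paste(sort(col[adj$children[[v]]], method = "radix"), collapse = "|"),
            paste(sort(col[adj$parents[[v]]], method = "radix"), collapse = "|"),
            sep = ";")
    }, character(1))
    new <- stats::setNames(match(sig, sort(unique(sig), method = "radix")),
                           g$vertices)
    old_part <- split(g$vertices, col[g$vertices])
    new_part <- split(g$vertices, new[g$vertices])
    if (length(old_part) == length(new_part)) {
      col <- stats::setNames(as.character(new), g$vertices)
      break
    }
    col <- stats::setNames(as.character(new), g$vertices)
  }
  col
}

# Canonical ordering of the vertices of a network via
# individualisation-refinement; returns list(order, code). Exponential only
# under large automorphism groups, which labelled leaves make rare.
canon_network <- function(g) {
  adj <- graph_adj(g)
  serialize <- function(ord) {
    idx <- stats::setNames(seq_along(ord), ord)
    labs <- vapply(ord, function(v) {
      lab <- g_label(g, v); if (is.na(lab)) "" else lab
    }, character(1))
    arcs <- paste(idx[g$arcs$tail], idx[g$arcs$head], sep = ">")
    paste(paste(labs, collapse = ","),
          paste(sort(arcs, method = "radix"), collapse = ";"),
          sep = "#")
  }
  rec <- function(col) {
    part <- split(g$vertices, col[g$vertices])
    sizes <- lengths(part)
    if (all(sizes == 1L)) {
      ord <- unlist(part[order(names(part), method = "radix")], use.names = FALSE)
      return(list(order = ord, code = serialize(ord)))
    }
    cell <- part[[which(sizes > 1L)[order(names(part)[sizes > 1L],
                                          method = "radix")][1L]]]
    cell_name <- names(part)[sizes > 1L][order(names(part)[sizes > 1L],
                                               method = "radix")][1L]
    best <- NULL
    for (v in sort(cell, method = "radix")) {
      col2 <- col
      col2[[v]] <- paste0(cell_name, "*")
      res <- rec(refine_colors(g, adj, col2))
      if (is.null(best) || res$code < best$code) best <- res
    }
    best
  }
  rec(refine_colors(g, adj, init_colors(g, adj)))
}

#' Isomorphism of X-networks
#'
#' Decides whether two X-networks on the same label set are isomorphic: a
#' vertex bijection preserving arc multiplicities and acting as the identity
#' on leaf labels. The test is exact (canonicalisation by colour refinement
#' with individualisation); when the answer is `TRUE` the attribute
#' `"witness"` carries one such bijection as a named character vector, and
#' when the label sets differ the attribute `"reason"` is `"label_sets"`.
#'
#' @param n1,n2 `phydag` networks.
#' @return Logical scalar with attributes as described.
#' @export
network_isomorphic <- function(n1, n2) {
  x1 <- sort(unname(n1$labels)); x2 <- sort(unname(n2$labels))
  if (!identical(x1, x2))
    return(structure(FALSE, reason = "label_sets"))
  if (length(n1$vertices) != length(n2$vertices) ||
      nrow(n1$arcs) != nrow(n2$arcs))
    return(structure(FALSE, reason = "size"))
  c1 <- canon_network(n1); c2 <- canon_network(n2)
  if (!identical(c1$code, c2$code))
    return(structure(FALSE, reason = "structure"))
  structure(TRUE, witness = stats::setNames(c2$order, c1$order))
}
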