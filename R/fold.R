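# Folding a MUL-tree into an X-network: inextendible subtree detection, the
# shrinking tree sequence, the guide tree (progressively subdivided pseudo
# tree), the equivalence by equal pseudo-subtree forms, and the quotient.

#' Repeated (inextendible) subtree classes of a MUL-tree
#'
#' A subtree is inextendible when an isomorphic copy occurs at two or more
#' distinct non-root vertices. Returns, for every such isomorphism class, the
#' canonical form and the full set of root vertices of its copies.
#' Subtrees are compared as pseudo MUL-trees (degree-two vertices, should the
#' input carry any, are significant and are not themselves class roots).
#'
#' @param t A `phydag` MUL-tree (or pseudo MUL-tree).
#' @return A named list: canonical form -> character vector of vertices.
#' @export
inextendible_roots <- function(t) {
  sc <- stats::setNames(integer(length(t$vertices)), t$vertices)
  inext_classes(t, sc)
}

# Scar-annotated canonical codes. `scars[v]` counts the subtree removals the
# shrinking sequence performed directly below v; two vertices are treated as
# isomorphic only when their scar patterns agree, so a vertex that lost a
# child can never be mistaken for a genuine copy of a smaller subtree.
scarred_codes <- function(t, scars) {
  adj <- graph_adj(t)
  ord <- topo_order(t, adj)
  if (is.null(ord)) stop("not an acyclic rooted graph")
  codes <- structure(character(length(t$vertices)), names = t$vertices)
  for (v in rev(ord)) {
    s <- scars[[v]]
    if (adj$outdeg[[v]] == 0L) {
      codes[[v]] <- paste0("L(", g_label(t, v), ")")
    } else if (s == 0L && v != t$root &&
               adj$indeg[[v]] == 1L && adj$outdeg[[v]] == 1L) {
      codes[[v]] <- paste0("D(", codes[[adj$children[[v]][[1L]]]], ")")
    } else {
      kids <- sort(codes[adj$children[[v]]], method = "radix")
      codes[[v]] <- paste0("I", if (s > 0L) paste0("[", s, "]") else "",
                           "(", paste(kids, collapse = ","), ")")
    }
  }
  codes
}

# Inextendible classes of the (possibly scarred) sequence tree: code classes
# with two or more members over the non-root vertices, excluding degree-two
# relic vertices (which root no subMUL-tree of their own).
inext_classes <- function(t, scars) {
  codes <- scarred_codes(t, scars)
  adj <- graph_adj(t)
  nonroot <- setdiff(t$vertices, t$root)
  nonroot <- nonroot[!(adj$outdeg[nonroot] == 1L & adj$indeg[nonroot] == 1L)]
  cls <- split(nonroot, codes[nonroot])
  cls[lengths(cls) >= 2L]
}

maximal_classes <- function(t, scars) {
  cls <- inext_classes(t, scars)
  if (!length(cls)) return(character(0))
  codes <- scarred_codes(t, scars)
  under <- lapply(cls, function(vs) {
    rep_v <- vs[[1L]]
    below <- setdiff(descendants_incl(t, rep_v), rep_v)
    unique(codes[below])
  })
  keep <- vapply(names(cls), function(cd) {
    !any(vapply(names(cls), function(other)
      other != cd && cd %in% under[[other]], logical(1)))
  }, logical(1))
  names(cls)[keep]
}

#' Maximal inextendible subtree classes
#'
#' The inextendible classes that are not properly contained, as subtrees, in
#' a larger non-isomorphic inextendible class.
#'
#' @param t A `phydag` MUL-tree.
#' @return Character vector of canonical forms.
#' @export
maximal_inextendible <- function(t) {
  sc <- stats::setNames(integer(length(t$vertices)), t$vertices)
  maximal_classes(t, sc)
}

# Remove the subtrees rooted at `drop` (with their incoming arcs) from a
# pseudo tree, deleting any unlabelled vertices left without children.
# Removals leave a permanent mark: degree-two vertices created by a removal
# are KEPT, and every vertex that loses a child gains a scar. Both measures
# stop a removal from turning a damaged vertex into an accidental copy of a
# genuine smaller subtree (suppressing and forgetting instead makes the
# final guide tree depend on the order of class choices).
prune_pseudo <- function(t, drop, scars) {
  adj0 <- graph_adj(t)
  for (w in drop) scars[[adj0$parents[[w]][[1L]]]] <-
    scars[[adj0$parents[[w]][[1L]]]] + 1L
  gone <- unique(unlist(lapply(drop, function(v) descendants_incl(t, v))))
  verts <- setdiff(t$vertices, gone)
  arcs <- t$arcs[t$arcs$tail %in% verts & t$arcs$head %in% verts, , drop = FALSE]
  g <- phydag(verts, arcs, t$root, t$labels)
  repeat {
    adj <- graph_adj(g)
    dead <- setdiff(names(adj$outdeg)[adj$outdeg == 0L &
                                      !(names(adj$outdeg) %in% names(g$labels))],
                    g$root)
    if (!length(dead)) break
    for (w in dead) scars[[adj$parents[[w]][[1L]]]] <-
      scars[[adj$parents[[w]][[1L]]]] + 1L
    verts <- setdiff(g$vertices, dead)
    g <- phydag(verts, g$arcs[g$arcs$head %in% verts, , drop = FALSE],
                g$root, g$labels)
  }
  list(tree = g, scars = scars[g$vertices])
}

# Suppressed, root-collapsed MUL-tree view of a pseudo tree (the form in
# which the shrinking sequence is reported).
as_multree <- function(t) {
  g <- t
  repeat {
    adj <- graph_adj(g)
    if (adj$outdeg[[g$root]] == 1L && length(g$vertices) > 1L) {
      child <- adj$children[[g$root]][[1L]]
      verts <- setdiff(g$vertices, g$root)
      g <- phydag(verts, g$arcs[g$arcs$tail != g$root, , drop = FALSE],
                  child, g$labels)
      next
    }
    g2 <- suppress_degree_two(g)
    if (length(g2$vertices) == length(g$vertices)) return(g2)
    g <- g2
  }
}

#' The shrinking tree sequence of the folding operation
#'
#' Iteratively selects a maximal inextendible subtree class, keeps one copy
#' and deletes the others together with their incoming arcs, until no
#' inextendible subtree remains. Internally the sequence is tracked as
#' pseudo MUL-trees with scar marks (see the methods vignette): a vertex
#' that lost a child is never again considered isomorphic to an undamaged
#' vertex, which is what makes the final guide tree independent of the
#' order of class choices. The reported `tau` trees are the suppressed,
#' root-collapsed MUL-tree views. Vertex ids are stable across the
#' sequence, so each step's chosen copy can be traced back to the input
#' tree.
#'
#' @param t A `phydag` MUL-tree.
#' @param order_policy Either `"lexicographic"` (default: always pick the
#'   class with the smallest canonical form, and keep the copy with the
#'   smallest vertex id) or a function `(candidate_forms, members)` returning
#'   a list with the chosen `code` and kept vertex `v` (used for
#'   order-invariance testing).
#' @return A list of class `fold_trace` with `tau` (the shrinking trees, in
#'   suppressed MUL-tree form), `pseudo` (the same trees with the degree-two
#'   vertices left by removals intact — the form the class detection runs
#'   on) and `chosen` (one record per step: `code`, `S`, `v`).
#' @export
fold_sequence <- function(t, order_policy = "lexicographic") {
  tau <- list(as_multree(t))
  pseudo <- list(t)
  chosen <- list()
  cur <- t
  scars <- stats::setNames(integer(length(t$vertices)), t$vertices)
  repeat {
    maxcls <- maximal_classes(cur, scars)
    if (!length(maxcls)) break
    cls <- inext_classes(cur, scars)
    if (is.function(order_policy)) {
      pick <- order_policy(sort(maxcls, method = "radix"), cls)
      code <- pick$code
      v <- pick$v
    } else {
      code <- sort(maxcls, method = "radix")[[1L]]
      v <- sort(cls[[code]], method = "radix")[[1L]]
    }
    S <- cls[[code]]
    chosen[[length(chosen) + 1L]] <- list(code = code, S = S, v = v)
    pr <- prune_pseudo(cur, setdiff(S, v), scars)
    cur <- pr$tree
    scars <- pr$scars
    pseudo[[length(pseudo) + 1L]] <- cur
    tau[[length(tau) + 1L]] <- as_multree(cur)
  }
  structure(list(tau = tau, pseudo = pseudo, chosen = chosen,
                 scars = scars), class = "fold_trace")
}

#' Build the guide tree of a fold trace
#'
#' Starting from the input MUL-tree, replays the fold steps: for each step,
#' every arc of the current (progressively subdivided) pseudo tree whose
#' head's pseudo-subtree is isomorphic to the pseudo-subtree at the step's
#' chosen root is subdivided by one fresh vertex. Comparisons are made as
#' pseudo MUL-trees, i.e. earlier subdivision vertices count.
#'
#' @param trace A `fold_trace` from [fold_sequence()].
#' @return A `phydag` pseudo MUL-tree (the guide tree), with the ids of the
#'   input tree preserved and subdivision vertices named `".s<i>"`.
#' @export
guide_tree <- function(trace) {
  g <- trace$tau[[1L]]
  counter <- 0L
  for (step in trace$chosen) {
    codes <- canonical_codes(g)
    ref <- codes[[step$v]]
    hit <- which(codes[g$arcs$head] == ref)
    if (!length(hit)) next
    arcs <- g$arcs
    new_ids <- character(0)
    for (i in hit) {
      counter <- counter + 1L
      s <- paste0(".s", counter)
      new_ids <- c(new_ids, s)
      arcs <- rbind(arcs,
                    data.frame(tail = arcs$tail[[i]], head = s, key = 0L,
                               stringsAsFactors = FALSE),
                    data.frame(tail = s, head = arcs$head[[i]], key = 0L,
                               stringsAsFactors = FALSE))
    }
    arcs <- arcs[-hit, , drop = FALSE]
    g <- phydag(c(g$vertices, new_ids), arcs, g$root, g$labels)
  }
  g
}

#' Fold a MUL-tree into an X-network
#'
#' Runs the complete folding pipeline: the shrinking tree sequence, the guide
#' tree, the partition of the guide tree's vertices into classes of equal
#' pseudo-subtree canonical forms, and the quotient with arc multiplicities
#' (parallel arcs can arise; the result is then an X-network but not a
#' phylogenetic network). The defining property that unfolding the result
#' returns a tree isomorphic to the input is asserted on every call.
#'
#' @param t A `phydag` MUL-tree.
#' @param order_policy Passed to [fold_sequence()].
#' @return A list of class `fold_result` with `result` (the folded
#'   `phydag`), `guide`, `partition` (list of blocks of guide-tree
#'   vertices), `quotient_raw` (the quotient before suppression), `trace`
#'   (the `fold_trace`) and `projection` (guide tree -> quotient).
#' @export
fold <- function(t, order_policy = "lexicographic") {
  trace <- fold_sequence(t, order_policy)
  guide <- guide_tree(trace)
  codes <- canonical_codes(guide)
  nonroot <- setdiff(guide$vertices, guide$root)
  part <- unname(split(nonroot, codes[nonroot]))
  part <- c(list(guide$root), part)
  q <- quotient_by_partition(guide, part)
  res <- q$network
  stopifnot(multree_isomorphic(unfold(res, cap = Inf), t))
  structure(list(result = res, guide = guide,
                 partition = q$blocks, quotient_raw = q$raw,
                 trace = trace, projection = q$projection),
            class = "fold_result")
}

#' Does folding a binary MUL-tree yield a phylogenetic network?
#'
#' For binary MUL-trees, the fold has no parallel arcs exactly when no two
#' subtrees rooted at siblings are isomorphic; this predicate checks the
#' sibling condition directly (without folding).
#'
#' @param t A binary `phydag` MUL-tree (every vertex has out-degree 0 or 2).
#' @return `TRUE` or `FALSE`.
#' @export
prop1_yields_network <- function(t) {
  adj <- graph_adj(t)
  if (!all(adj$outdeg %in% c(0L, 2L)))
    stop("this criterion is defined for binary MUL-trees only")
  codes <- canonical_codes(t)
  for (v in names(adj$outdeg)[adj$outdeg > 0L]) {
    kids <- adj$children[[v]]
    if (anyDuplicated(codes[kids])) return(FALSE)
  }
  TRUE
}
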