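# Displaying trees in networks: brute-force display (over reticulation arc
# selections), display inside a MUL-tree (embedding search, the oracle for
# the dynamic program), the weak-display dynamic program with reconciliation
# witnesses, and the HangLeaves reduction to binary compressed tree-sibling
# instances.

is_binary_network <- function(n) {
  adj <- graph_adj(n)
  rets <- names(adj$indeg)[adj$indeg >= 2L]
  internal <- setdiff(names(adj$indeg)[adj$outdeg > 0L], c(n$root, rets))
  all(adj$indeg[rets] == 2L) && all(adj$outdeg[rets] == 1L) &&
    all(adj$outdeg[internal] == 2L) && adj$outdeg[[n$root]] == 2L
}

# Clean a subgraph after an arc selection: drop unlabelled dead ends, trim a
# root left with out-degree <= 1 onto its child, then suppress.
clean_to_tree <- function(g) {
  repeat {
    adj <- graph_adj(g)
    dead <- setdiff(names(adj$outdeg)[adj$outdeg == 0L &
                                      !(names(adj$outdeg) %in% names(g$labels))],
                    character(0))
    dead <- setdiff(dead, g$root)
    if (length(dead)) {
      verts <- setdiff(g$vertices, dead)
      g <- phydag(verts, g$arcs[g$arcs$head %in% verts &
                                g$arcs$tail %in% verts, , drop = FALSE],
                  g$root, g$labels)
      next
    }
    if (adj$outdeg[[g$root]] == 1L && length(g$vertices) > 1L) {
      child <- adj$children[[g$root]][[1L]]
      verts <- setdiff(g$vertices, g$root)
      g <- phydag(verts, g$arcs[g$arcs$tail != g$root, , drop = FALSE],
                  child, g$labels)
      next
    }
    return(suppress_degree_two(g))
  }
}

#' Is a tree displayed by a network? (brute force)
#'
#' Enumerates, for every reticulation, the choice of one incoming arc to
#' keep; each choice induces a subgraph which, after removing dead ends and
#' suppressing degree-two vertices, is a phylogenetic tree on the same label
#' set. The tree is displayed exactly when some choice yields a tree
#' isomorphic to it. When the answer is `TRUE`, the attribute `"witness"`
#' holds the un-suppressed selected subgraph (a subdivision of `t`).
#'
#' @param n A binary `phydag` phylogenetic network.
#' @param t A binary `phydag` phylogenetic tree on the same label set.
#' @param max_ret Refuse instances with more reticulations than this (the
#'   enumeration is exponential).
#' @return Logical scalar, with attribute `"witness"` when `TRUE`.
#' @export
displays <- function(n, t, max_ret = 12L) {
  if (!is_binary_network(n) || !is_binary_network(t))
    stop("brute-force display testing is implemented for binary inputs only")
  adj <- graph_adj(n)
  rets <- names(adj$indeg)[adj$indeg >= 2L]
  if (length(rets) > max_ret)
    stop(sprintf("network has %d reticulations, above the bound of %d",
                 length(rets), max_ret))
  target <- canonical_form(t)
  in_rows <- lapply(rets, function(r) which(n$arcs$head == r))
  grid <- if (length(rets)) do.call(expand.grid, in_rows) else
    data.frame(row.names = 1L)
  for (i in seq_len(max(nrow(grid), 1L))) {
    keep_rows <- setdiff(seq_len(nrow(n$arcs)),
                         setdiff(unlist(in_rows),
                                 if (length(rets)) unlist(grid[i, ]) else integer(0)))
    g <- phydag(n$vertices, n$arcs[keep_rows, , drop = FALSE], n$root, n$labels)
    # selection keeps every vertex reachable; restrict to the root component
    keep <- descendants_incl(g, g$root)
    g <- phydag(keep, g$arcs[g$arcs$tail %in% keep & g$arcs$head %in% keep,
                             , drop = FALSE], g$root, g$labels)
    pruned <- clean_to_tree(g)
    if (identical(canonical_form(pruned), target)) {
      witness <- witness_subdivision(g)
      return(structure(TRUE, witness = witness))
    }
  }
  FALSE
}

# The selected subgraph restricted to root-to-leaf paths and root-trimmed,
# i.e. a subdivision of the displayed tree (no suppression).
witness_subdivision <- function(g) {
  repeat {
    adj <- graph_adj(g)
    dead <- setdiff(names(adj$outdeg)[adj$outdeg == 0L &
                                      !(names(adj$outdeg) %in% names(g$labels))],
                    g$root)
    if (length(dead)) {
      verts <- setdiff(g$vertices, dead)
      g <- phydag(verts, g$arcs[g$arcs$head %in% verts &
                                g$arcs$tail %in% verts, , drop = FALSE],
                  g$root, g$labels)
      next
    }
    if (adj$outdeg[[g$root]] == 1L && length(g$vertices) > 1L) {
      child <- adj$children[[g$root]][[1L]]
      verts <- setdiff(g$vertices, g$root)
      g <- phydag(verts, g$arcs[g$arcs$tail != g$root, , drop = FALSE],
                  child, g$labels)
      next
    }
    return(g)
  }
}

#' Is a tree displayed inside a MUL-tree?
#'
#' Searches for a subgraph of the MUL-tree that is a subdivision of `t`,
#' matching the leaves of `t` injectively to same-labelled leaves of the
#' MUL-tree. This is a direct embedding search on the MUL-tree and serves as
#' the independent check for [weakly_displays()].
#'
#' @param mt A `phydag` MUL-tree.
#' @param t A binary `phydag` phylogenetic tree on the same label set.
#' @return `TRUE` or `FALSE`.
#' @export
displays_in_multree <- function(mt, t) {
  adj_m <- graph_adj(mt)
  adj_t <- graph_adj(t)
  memo_at <- new.env(parent = emptyenv())
  memo_below <- new.env(parent = emptyenv())
  embed_at <- function(v, u) {
    k <- paste(v, u, sep = "\r")
    hit <- memo_at[[k]]
    if (!is.null(hit)) return(hit)
    res <- if (adj_t$outdeg[[v]] == 0L) {
      identical(g_label(mt, u), g_label(t, v))
    } else if (adj_m$outdeg[[u]] < 2L) {
      FALSE
    } else {
      kids_v <- adj_t$children[[v]]
      kids_u <- adj_m$children[[u]]
      found <- FALSE
      for (c1 in kids_u) {
        for (c2 in setdiff(kids_u, c1)) {
          if (embed_below(kids_v[[1L]], c1) && embed_below(kids_v[[2L]], c2)) {
            found <- TRUE; break
          }
        }
        if (found) break
      }
      found
    }
    memo_at[[k]] <- res
    res
  }
  embed_below <- function(v, u) {
    k <- paste(v, u, sep = "\r")
    hit <- memo_below[[k]]
    if (!is.null(hit)) return(hit)
    res <- embed_at(v, u) ||
      any(vapply(adj_m$children[[u]], function(c) embed_below(v, c), logical(1)))
    memo_below[[k]] <- res
    res
  }
  embed_below(t$root, mt$root)
}

#' Is a tree weakly displayed by a network? (dynamic program)
#'
#' A tree is weakly displayed by a network when the network's unfolding
#' displays it; equivalently, when a locally separated reconciliation
#' between tree and network exists. This decides the question in
#' `O(|V(T)| * |V(N)| * k)` table updates (with `k` the maximum out-degree of
#' the network) by filling an indicator table `tau(v, u)` over topological
#' orderings: a leaf row is 1 where its label is at or below `u`; an interior
#' row is 1 where some child of `u` already carries 1, or two distinct
#' children of `u` carry the two child subtrees.
#'
#' @param n A `phydag` phylogenetic network.
#' @param t A binary `phydag` phylogenetic tree on the same label set.
#' @return Logical scalar of the answer `tau(root, root)`, with attribute
#'   `"table"`: a list of class `dp_table` with the 0/1 matrix `tau`
#'   (rows = tree vertices, columns = network vertices), backpointers
#'   `back`, and the update count `updates`.
#' @export
weakly_displays <- function(n, t) {
  adj_t <- graph_adj(t)
  if (!all(adj_t$outdeg %in% c(0L, 2L)))
    stop("the dynamic program requires a binary tree")
  adj_n <- graph_adj(n)
  ord_t <- rev(topo_order(t, adj_t))
  ord_n <- rev(topo_order(n, adj_n))
  tau <- matrix(0L, nrow = length(ord_t), ncol = length(ord_n),
                dimnames = list(ord_t, ord_n))
  back <- list()
  updates <- 0L
  for (v in ord_t) {
    v_leaf <- adj_t$outdeg[[v]] == 0L
    kids_v <- adj_t$children[[v]]
    for (u in ord_n) {
      kids_u <- sort(unique(adj_n$children[[u]]), method = "radix")
      updates <- updates + max(1L, length(kids_u))
      if (v_leaf) {
        lab <- g_label(t, v)
        if (identical(g_label(n, u), lab)) {
          tau[v, u] <- 1L
          back[[paste(v, u, sep = "\r")]] <- list(type = "leaf_here")
        } else {
          hit <- kids_u[tau[v, kids_u] == 1L]
          if (length(hit)) {
            tau[v, u] <- 1L
            back[[paste(v, u, sep = "\r")]] <-
              list(type = "descend", child = hit[[1L]])
          }
        }
      } else {
        if (length(kids_u)) {
          hit <- kids_u[tau[v, kids_u] == 1L]
          if (length(hit)) {
            tau[v, u] <- 1L
            back[[paste(v, u, sep = "\r")]] <-
              list(type = "descend", child = hit[[1L]])
            next
          }
          if (length(kids_u) >= 2L) {
            done <- FALSE
            for (u1 in kids_u) {
              for (u2 in setdiff(kids_u, u1)) {
                updates <- updates + 1L
                if (tau[kids_v[[1L]], u1] == 1L && tau[kids_v[[2L]], u2] == 1L) {
                  tau[v, u] <- 1L
                  back[[paste(v, u, sep = "\r")]] <-
                    list(type = "split", u1 = u1, u2 = u2)
                  done <- TRUE; break
                }
              }
              if (done) break
            }
          }
        }
      }
    }
  }
  ans <- tau[t$root, n$root] == 1L
  structure(ans, table = structure(list(tau = tau, back = back,
                                        updates = updates,
                                        m = length(ord_t), n = length(ord_n),
                                        k = max(c(0L, adj_n$outdeg))),
                                   class = "dp_table"))
}

#' Extract a locally separated reconciliation from the dynamic program
#'
#' Follows the backpointers of [weakly_displays()] to build a reconciliation
#' map: a vertex map `r` from the tree into the tree vertices (plus root) of
#' the network, and one directed path of the network per tree arc. Extracted
#' maps are locally separated by construction and satisfy
#' [verify_reconciliation()].
#'
#' @param n,t As in [weakly_displays()].
#' @param dp Optional result of `weakly_displays(n, t)` to reuse.
#' @return A list of class `reconciliation` with `r` (named character
#'   vector) and `paths` (named list: tree arc id -> character vector of
#'   network arc ids), or `NULL` when `t` is not weakly displayed.
#' @export
reconciliation <- function(n, t, dp = NULL) {
  if (is.null(dp)) dp <- weakly_displays(n, t)
  if (!isTRUE(c(dp))) return(NULL)
  tab <- attr(dp, "table")
  back <- tab$back
  adj_t <- graph_adj(t)
  r <- stats::setNames(rep(NA_character_, length(t$vertices)), t$vertices)
  paths <- list()
  follow <- function(v, u) {
    prefix <- character(0)
    repeat {
      bp <- back[[paste(v, u, sep = "\r")]]
      if (is.null(bp)) stop("internal error: missing backpointer")
      if (bp$type == "descend") {
        prefix <- c(prefix, arc_id(u, bp$child, arc_key(n, u, bp$child)))
        u <- bp$child
      } else break
    }
    list(at = u, prefix = prefix)
  }
  walk <- function(v, u) {
    stopifnot(tab$tau[v, u] == 1L)
    fx <- follow(v, u)
    r[[v]] <<- fx$at
    bp <- back[[paste(v, fx$at, sep = "\r")]]
    if (bp$type == "split") {
      kids <- adj_t$children[[v]]
      for (i in 1:2) {
        ui <- if (i == 1L) bp$u1 else bp$u2
        first <- arc_id(fx$at, ui, arc_key(n, fx$at, ui))
        sub <- walk(kids[[i]], ui)
        paths[[arc_id(v, kids[[i]], arc_key(t, v, kids[[i]])) ]] <<-
          c(first, sub)
      }
    }
    fx$prefix
  }
  walk(t$root, n$root)
  structure(list(r = r, paths = paths), class = "reconciliation")
}

arc_key <- function(g, tail, head) {
  k <- g$arcs$key[g$arcs$tail == tail & g$arcs$head == head]
  if (!length(k)) stop(sprintf("no arc %s -> %s", tail, head))
  min(k)
}

#' Verify a reconciliation map
#'
#' Checks the reconciliation axioms — images are tree vertices or the root,
#' leaves map to their labels' leaves, and every tree arc carries a genuine
#' directed path of the network with the right endpoints — plus local
#' separation: the two paths leaving a vertex towards its children each
#' contain at least one arc, and their initial arcs differ.
#'
#' @param rec A `reconciliation` (or a bare list with `r` and `paths`).
#' @param t,n The tree and network.
#' @return A list with `ok`, `locally_separated` and `violations`.
#' @export
verify_reconciliation <- function(rec, t, n) {
  bad <- character(0)
  adj_n <- graph_adj(n)
  adj_t <- graph_adj(t)
  v_tr <- c(n$root, setdiff(
    n$vertices[adj_n$indeg == 1L & adj_n$outdeg != 1L], n$root))
  miss <- setdiff(t$vertices, names(rec$r)[!is.na(rec$r)])
  if (length(miss))
    bad <- c(bad, paste0("r undefined on: ", paste(miss, collapse = ", ")))
  else {
    outside <- t$vertices[!(rec$r[t$vertices] %in% v_tr)]
    if (length(outside))
      bad <- c(bad, paste0("r maps outside the tree vertices of the network: ",
                           paste(outside, collapse = ", ")))
    for (lf in names(t$labels)) {
      img <- rec$r[[lf]]
      if (!identical(g_label(n, img), t$labels[[lf]]))
        bad <- c(bad, sprintf("leaf '%s' maps to '%s', not its label's leaf",
                              lf, img))
    }
    na <- arc_ids(n)
    for (i in seq_len(nrow(t$arcs))) {
      aid <- arc_id(t$arcs$tail[[i]], t$arcs$head[[i]], t$arcs$key[[i]])
      p <- rec$paths[[aid]]
      if (is.null(p)) {
        bad <- c(bad, paste0("no path stored for tree arc ", aid))
        next
      }
      if (length(p)) {
        seg <- split_arc_id(p)
        if (!all(p %in% na))
          bad <- c(bad, paste0("path for ", aid, " uses unknown arcs"))
        else {
          chain <- all(seg$tail[-1L] == seg$head[-nrow(seg)])
          if (!chain || seg$tail[[1L]] != rec$r[[t$arcs$tail[[i]]]] ||
              seg$head[[nrow(seg)]] != rec$r[[t$arcs$head[[i]]]])
            bad <- c(bad, paste0("path for ", aid,
                                 " is not a directed path from r(tail) to r(head)"))
        }
      } else if (rec$r[[t$arcs$tail[[i]]]] != rec$r[[t$arcs$head[[i]]]]) {
        bad <- c(bad, paste0("empty path for ", aid,
                             " but endpoints map to different vertices"))
      }
    }
  }
  sep_ok <- TRUE
  for (v in t$vertices[adj_t$outdeg > 0L]) {
    kids <- adj_t$children[[v]]
    firsts <- character(0)
    for (w in kids) {
      aid <- arc_id(v, w, arc_key(t, v, w))
      p <- rec$paths[[aid]]
      if (is.null(p) || !length(p)) { sep_ok <- FALSE; next }
      firsts <- c(firsts, p[[1L]])
    }
    if (length(firsts) < length(kids) || anyDuplicated(firsts)) {
      sep_ok <- FALSE
      bad <- c(bad, sprintf("paths leaving '%s' are not locally separated", v))
    }
  }
  list(ok = length(bad) == 0L && sep_ok, locally_separated = sep_ok,
       violations = bad)
}

#' Turn a reconciliation into a subdivision X-morphism
#'
#' A reconciliation associates a directed network path with every tree arc;
#' subdividing each tree arc once per interior vertex of its path yields a
#' subdivision of the tree together with an X-morphism into the network.
#'
#' @param rec A `reconciliation` between `t` and `n`.
#' @param t,n The tree and network.
#' @return A list with `tstar` (the subdivided tree, a `phydag`) and
#'   `morphism` (an `xmorphism` from `tstar` to `n`).
#' @export
reconciliation_morphism <- function(rec, t, n) {
  verts <- t$vertices
  labels <- t$labels
  vmap <- rec$r[t$vertices]
  amap <- character(0)
  tails <- character(0); heads <- character(0)
  k <- 0L
  for (i in seq_len(nrow(t$arcs))) {
    u <- t$arcs$tail[[i]]; v <- t$arcs$head[[i]]
    aid <- arc_id(u, v, t$arcs$key[[i]])
    p <- rec$paths[[aid]]
    seg <- split_arc_id(p)
    cur <- u
    for (j in seq_len(nrow(seg))) {
      nxt <- if (j == nrow(seg)) v else {
        k <- k + 1L
        w <- paste0(".sd", k)
        verts <- c(verts, w)
        vmap[[w]] <- seg$head[[j]]
        w
      }
      tails <- c(tails, cur); heads <- c(heads, nxt)
      amap[[arc_id(cur, nxt, 0L)]] <- p[[j]]
      cur <- nxt
    }
  }
  tstar <- phydag(verts, data.frame(tail = tails, head = heads,
                                    stringsAsFactors = FALSE),
                  t$root, labels)
  list(tstar = tstar, morphism = xmorphism(vmap, amap))
}

# ---------------------------------------------------------------------------
# HangLeaves and the reduction to stable instances.

#' Attach the HangLeaves gadget at a vertex
#'
#' Adds five vertices (`x_v`, `x_v'`, `p_v`, `q_v`, `rho_v`) and six arcs to
#' the network — a new root `rho_v` above the old one, a reticulation `q_v`
#' fed by `p_v` and by `v`, and two fresh leaves — and, in concert, four
#' vertices and four arcs to the tree. Both structures gain the two fresh
#' labels.
#'
#' @param n A `phydag` network; @param r A `phydag` tree on the same labels.
#' @param v A vertex of `n`.
#' @param tag Base string for the fresh vertex ids and labels (must be new).
#' @return A list with `network`, `tree` and `new_labels` (character(2)).
#' @export
hang_leaves <- function(n, r, v, tag = v) {
  xv <- paste0("x_", tag); xv2 <- paste0("xp_", tag)
  pv <- paste0("p_", tag); qv <- paste0("q_", tag); rv <- paste0("rho_", tag)
  clash <- intersect(c(xv, xv2, pv, qv, rv), c(n$vertices, r$vertices))
  if (length(clash) || any(c(xv, xv2) %in% c(n$labels, r$labels)))
    stop("fresh ids/labels collide: ", paste(clash, collapse = ", "))
  n2 <- phydag(c(n$vertices, xv, xv2, pv, qv, rv),
               rbind(n$arcs,
                     data.frame(tail = c(rv, rv, pv, v, pv, qv),
                                head = c(n$root, pv, qv, qv, xv2, xv),
                                key = 0L, stringsAsFactors = FALSE)),
               rv, c(n$labels, stats::setNames(c(xv, xv2), c(xv, xv2))))
  r2 <- phydag(c(r$vertices, xv, xv2, rv, pv),
               rbind(r$arcs,
                     data.frame(tail = c(rv, rv, pv, pv),
                                head = c(r$root, pv, xv, xv2),
                                key = 0L, stringsAsFactors = FALSE)),
               rv, c(r$labels, stats::setNames(c(xv, xv2), c(xv, xv2))))
  list(network = n2, tree = r2, new_labels = c(xv, xv2))
}

subdivide_arc <- function(g, tail, head, key, id) {
  i <- which(g$arcs$tail == tail & g$arcs$head == head & g$arcs$key == key)
  if (length(i) != 1L) stop("arc not found")
  phydag(c(g$vertices, id),
         rbind(g$arcs[-i, , drop = FALSE],
               data.frame(tail = c(tail, id), head = c(id, head), key = 0L,
                          stringsAsFactors = FALSE)),
         g$root, g$labels)
}

#' Reduce a display instance to an equivalent stable instance
#'
#' Transforms a binary display instance `(n, t)` into `(n*, t*)` on an
#' enlarged label set such that `n*` is binary, compressed and tree-sibling
#' (hence stable), and `t` is displayed by `n` exactly when `t*` is
#' displayed by `n*`. Step one subdivides every arc whose head is a
#' reticulation and hangs fresh leaves at the subdivision vertex; step two,
#' for every original reticulation, subdivides the arc to one of its (now
#' reticulate) siblings and hangs fresh leaves there, creating the missing
#' tree sibling.
#'
#' @param n A binary `phydag` phylogenetic network.
#' @param t A binary `phydag` phylogenetic tree on the same labels.
#' @return A list with `network` (`n*`), `tree` (`t*`) and `added_labels`.
#' @export
stable_instance <- function(n, t) {
  if (!is_binary_network(n) || !is_binary_network(t))
    stop("the reduction is defined for binary instances")
  adj <- graph_adj(n)
  rets <- sort(names(adj$indeg)[adj$indeg >= 2L], method = "radix")
  added <- character(0)
  ncur <- n; tcur <- t
  step <- 0L
  # Step 1: one gadget per arc into a reticulation.
  ret_arcs <- ncur$arcs[ncur$arcs$head %in% rets, , drop = FALSE]
  ret_arcs <- ret_arcs[order(ret_arcs$tail, ret_arcs$head, ret_arcs$key,
                             method = "radix"), , drop = FALSE]
  sub_of <- list()   # reticulation -> ids of its subdivision parents
  for (i in seq_len(nrow(ret_arcs))) {
    step <- step + 1L
    ve <- paste0("s", step)
    ncur <- subdivide_arc(ncur, ret_arcs$tail[[i]], ret_arcs$head[[i]],
                          ret_arcs$key[[i]], ve)
    hl <- hang_leaves(ncur, tcur, ve, tag = ve)
    ncur <- hl$network; tcur <- hl$tree
    added <- c(added, hl$new_labels)
    r <- ret_arcs$head[[i]]
    sub_of[[r]] <- c(sub_of[[r]], ve)
  }
  # Step 2: give every original reticulation a tree sibling.
  for (r in rets) {
    step <- step + 1L
    pe <- sort(sub_of[[r]], method = "radix")[[1L]]   # one joint parent of r
    sib <- paste0("q_", pe)                           # its reticulate sibling
    vs <- paste0("s", step)
    ncur <- subdivide_arc(ncur, pe, sib, 0L, vs)
    hl <- hang_leaves(ncur, tcur, vs, tag = vs)
    ncur <- hl$network; tcur <- hl$tree
    added <- c(added, hl$new_labels)
  }
  props <- net_properties(ncur)
  stopifnot(props$binary, props$compressed, props$tree_sibling)
  list(network = ncur, tree = tcur, added_labels = added)
}
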