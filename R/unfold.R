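# Unfolding a network into the pseudo MUL-tree of its root paths, the
# suppressed MUL-tree, and the canonical folding map onto the network.

#' Unfold a network into its tree of root paths
#'
#' Builds the pseudo MUL-tree whose vertices are the directed paths of `n`
#' starting at the root (the empty path included), with an arc from path
#' `pi` to `pi'` exactly when `pi'` extends `pi` by one arc of `n`. Paths
#' ending at a leaf labelled `x` become leaves labelled `x`. Also returns the
#' suppressed MUL-tree and the canonical folding map that sends every path to
#' its last vertex and every arc to the extending arc.
#'
#' @param n A `phydag` network (parallel arcs allowed).
#' @param cap Maximum number of path vertices materialised before failing
#'   (the number of root paths can grow exponentially in the number of
#'   reticulations).
#' @return A list of class `unfold_result` with fields `ustar` (pseudo
#'   MUL-tree of root paths), `u` (the suppressed MUL-tree), `fstar` (an
#'   `xmorphism` from `ustar` to `n`) and `correspondence` (named vector
#'   mapping the vertices of `u` to the same-named vertices of `ustar`).
#' @export
unfold_star <- function(n, cap = 1e5) {
  adj <- graph_adj(n)
  arcs <- n$arcs[order(n$arcs$tail, n$arcs$head, n$arcs$key,
                       method = "radix"), , drop = FALSE]
  out_by_tail <- split(seq_len(nrow(arcs)), factor(arcs$tail, n$vertices))

  end <- n$root            # end vertex of each path vertex
  parent <- NA_integer_    # index of parent path
  via <- NA_integer_       # row of `arcs` used to extend the parent
  i <- 1L
  while (i <= length(end)) {
    rows <- out_by_tail[[end[[i]]]]
    if (length(rows)) {
      end <- c(end, arcs$head[rows])
      parent <- c(parent, rep(i, length(rows)))
      via <- c(via, rows)
      if (length(end) > cap)
        stop(sprintf(paste0("unfolding exceeds the cap of %d path vertices; ",
                            "raise `cap` if this is intended"), cap),
             call. = FALSE)
    }
    i <- i + 1L
  }
  ids <- paste0("p", seq_along(end))
  tails <- ids[parent[-1L]]
  heads <- ids[-1L]
  leaf_idx <- which(lengths(out_by_tail[end]) == 0L)
  labels <- stats::setNames(unname(n$labels[end[leaf_idx]]), ids[leaf_idx])
  ustar <- phydag(ids,
                  data.frame(tail = tails, head = heads,
                             stringsAsFactors = FALSE),
                  "p1", labels)
  vmap <- stats::setNames(end, ids)
  amap <- stats::setNames(arc_id(arcs$tail[via[-1L]], arcs$head[via[-1L]],
                                 arcs$key[via[-1L]]),
                          arc_id(tails, heads, 0L))
  fstar <- xmorphism(vmap, amap)
  u <- suppress_degree_two(ustar)
  structure(list(ustar = ustar, u = u, fstar = fstar,
                 correspondence = stats::setNames(u$vertices, u$vertices)),
            class = "unfold_result")
}

#' Unfold a network into a MUL-tree
#'
#' The MUL-tree obtained by suppressing all degree-two vertices in the tree
#' of root paths.
#'
#' @inheritParams unfold_star
#' @return A `phydag` MUL-tree.
#' @export
unfold <- function(n, cap = 1e5) unfold_star(n, cap)$u

#' Does a network exhibit a MUL-tree?
#'
#' A network exhibits `t` when its unfolding is isomorphic to `t`.
#'
#' @inheritParams unfold_star
#' @param t A `phydag` MUL-tree.
#' @return `TRUE` or `FALSE`.
#' @export
exhibits <- function(n, t, cap = 1e5) multree_isomorphic(unfold(n, cap), t)
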