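# Seeded random generators for binary trees, MUL-trees and networks, with
# constraint filters. Every test input of the package is produced here; no
# external data is needed. All randomness flows through R's RNG; functions
# accept an explicit seed and restore the caller's RNG state on exit.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

fresh_ids <- function(prefix, k, avoid) {
  out <- character(0); i <- 0L
  while (length(out) < k) {
    i <- i + 1L
    cand <- paste0(prefix, i)
    if (!cand %in% avoid) out <- c(out, cand)
  }
  out
}

#' Random binary phylogenetic tree
#'
#' Grows a rooted binary tree by sequential random leaf attachment: each new
#' leaf is attached by subdividing a uniformly chosen arc (or above the
#' root). The result has exactly `2|x| - 1` vertices.
#'
#' @param x Character vector of leaf labels (at least two, distinct).
#' @param seed Optional integer seed.
#' @return A `phydag` binary phylogenetic tree on `x`.
#' @export
random_binary_tree <- function(x, seed = NULL) {
  if (length(x) < 2L || anyDuplicated(x)) stop("need >= 2 distinct labels")
  with_seed(seed, {
    g <- phydag(c("i1", x[[1L]], x[[2L]]),
                data.frame(tail = "i1", head = c(x[[1L]], x[[2L]]),
                           stringsAsFactors = FALSE),
                "i1", stats::setNames(x[1:2], x[1:2]))
    for (j in seq_along(x)[-(1:2)]) {
      leaf <- x[[j]]
      pos <- sample.int(nrow(g$arcs) + 1L, 1L)
      new_int <- fresh_ids("i", 1L, c(g$vertices, x))
      if (pos > nrow(g$arcs)) {            # attach above the root
        g <- phydag(c(g$vertices, new_int, leaf),
                    rbind(g$arcs,
                          data.frame(tail = new_int, head = c(g$root, leaf),
                                     key = 0L, stringsAsFactors = FALSE)),
                    new_int, c(g$labels, stats::setNames(leaf, leaf)))
      } else {
        a <- g$arcs[pos, ]
        g <- phydag(c(g$vertices, new_int, leaf),
                    rbind(g$arcs[-pos, , drop = FALSE],
                          data.frame(tail = c(a$tail, new_int, new_int),
                                     head = c(new_int, a$head, leaf),
                                     key = 0L, stringsAsFactors = FALSE)),
                    g$root, c(g$labels, stats::setNames(leaf, leaf)))
      }
    }
    g
  })
}

#' Random phylogenetic network
#'
#' Starts from a random binary tree and adds reticulations one at a time by
#' subdividing two arcs and connecting the subdivision vertices (the
#' connection respects reachability, so the result stays acyclic). When
#' `"compressed"` is among the constraints, arcs incident to reticulations
#' are never chosen as the target of a new reticulation arc, which keeps
#' every reticulation's child a tree vertex.
#' Remaining constraints (`"tree_child"`, `"tree_sibling"`,
#' `"semi_resolved"`, `"binary"`) are enforced by rejection sampling up to
#' `max_tries` attempts. Without `"binary"`, a fraction of internal tree
#' arcs is contracted to create multifurcations, and extra parents may be
#' added to existing reticulations.
#'
#' @param x Character vector of leaf labels.
#' @param reticulations Number of reticulation events to add.
#' @param constraints Character subset of `c("binary", "compressed",
#'   "tree_child", "tree_sibling", "semi_resolved")`.
#' @param seed Optional integer seed.
#' @param max_tries Attempts before giving up on the constraint set.
#' @param contract_prob With `"binary"` absent: probability of contracting
#'   each internal tree arc (multifurcation).
#' @param extra_parent_prob With `"binary"` absent: probability that a
#'   reticulation event reuses an existing reticulation (raising its
#'   in-degree) instead of creating a new one.
#' @return A `phydag` phylogenetic network satisfying the constraints.
#' @export
random_network <- function(x, reticulations = 2L,
                           constraints = character(),
                           seed = NULL, max_tries = 200L,
                           contract_prob = 0.25,
                           extra_parent_prob = 0.25) {
  ok_constraints <- c("binary", "compressed", "tree_child", "tree_sibling",
                      "semi_resolved")
  if (!all(constraints %in% ok_constraints))
    stop("unknown constraints: ",
         paste(setdiff(constraints, ok_constraints), collapse = ", "))
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      g <- try_random_network(x, reticulations, constraints,
                              contract_prob, extra_parent_prob)
      if (is.null(g)) next
      if (!validate_graph(g, "phylo_network")$ok) next
      props <- net_properties(g)
      want <- constraints
      if (all(vapply(want, function(cn) isTRUE(props[[cn]]), logical(1))))
        return(g)
    }
    stop("could not satisfy constraints ",
         paste(constraints, collapse = ","), " in ", max_tries, " tries")
  })
}

try_random_network <- function(x, reticulations, constraints,
                               contract_prob, extra_parent_prob) {
  compressed <- "compressed" %in% constraints
  allow_reuse <- !("binary" %in% constraints)
  do_contract <- !("binary" %in% constraints) &&
    !("semi_resolved" %in% constraints)
  g <- random_binary_tree(x)
  rets <- character(0)
  for (k in seq_len(reticulations)) {
    adj <- graph_adj(g)
    reuse <- allow_reuse && length(rets) && stats::runif(1) < extra_parent_prob
    # candidate target arcs (the head side becomes / is a reticulation)
    arc_tbl <- g$arcs
    ret_incident <- arc_tbl$head %in% rets | arc_tbl$tail %in% rets
    cand_t <- if (compressed) which(!ret_incident) else seq_len(nrow(arc_tbl))
    if (reuse) {
      r <- rets[[sample.int(length(rets), 1L)]]
      # new source arc: subdividing (u, v) by s and adding s -> r is acyclic
      # iff u is not below r; (u, r) itself would create parallel arcs
      below_r <- descendants_incl(g, r, adj)
      cand_s <- which(!(arc_tbl$tail %in% below_r) & arc_tbl$head != r)
      if (!length(cand_s)) return(NULL)
      i <- cand_s[[sample.int(length(cand_s), 1L)]]
      s1 <- fresh_ids("u", 1L, g$vertices)
      g <- subdivide_arc(g, arc_tbl$tail[[i]], arc_tbl$head[[i]],
                         arc_tbl$key[[i]], s1)
      g <- phydag(g$vertices,
                  rbind(g$arcs, data.frame(tail = s1, head = r, key = 0L,
                                           stringsAsFactors = FALSE)),
                  g$root, g$labels)
      next
    }
    if (length(cand_t) < 1L) return(NULL)
    i2 <- cand_t[[sample.int(length(cand_t), 1L)]]
    head2 <- arc_tbl$head[[i2]]
    # source arc: must not make the new arc create a cycle, i.e. the target
    # head must not reach the source tail; also not the same arc
    ok_src <- vapply(seq_len(nrow(arc_tbl)), function(i) {
      i != i2 &&
        !(arc_tbl$tail[[i]] %in% descendants_incl(g, head2, adj)) &&
        arc_tbl$tail[[i]] != head2
    }, logical(1))
    cand_s <- which(ok_src)
    if (!length(cand_s)) return(NULL)
    i1 <- cand_s[[sample.int(length(cand_s), 1L)]]
    ids <- fresh_ids("u", 2L, g$vertices)
    s1 <- ids[[1L]]; s2 <- ids[[2L]]
    a1 <- arc_tbl[i1, ]; a2 <- arc_tbl[i2, ]
    g <- subdivide_arc(g, a1$tail, a1$head, a1$key, s1)
    g <- subdivide_arc(g, a2$tail, a2$head, a2$key, s2)
    g <- phydag(g$vertices,
                rbind(g$arcs, data.frame(tail = s1, head = s2, key = 0L,
                                         stringsAsFactors = FALSE)),
                g$root, g$labels)
    rets <- c(rets, s2)
  }
  if (do_contract) {
    # contract some internal tree arcs into multifurcations
    repeat {
      adj <- graph_adj(g)
      rets_now <- names(adj$indeg)[adj$indeg >= 2L]
      tree_arcs <- which(
        !(g$arcs$head %in% rets_now) & adj$outdeg[g$arcs$head] >= 2L &
          !(g$arcs$tail %in% rets_now))
      # contracting (u, v) must not give u and v a shared child
      tree_arcs <- Filter(function(i) {
        u <- g$arcs$tail[[i]]; v <- g$arcs$head[[i]]
        !length(intersect(adj$children[[u]], adj$children[[v]]))
      }, tree_arcs)
      tree_arcs <- tree_arcs[stats::runif(length(tree_arcs)) < contract_prob]
      if (!length(tree_arcs)) break
      i <- tree_arcs[[1L]]
      u <- g$arcs$tail[[i]]; v <- g$arcs$head[[i]]
      arcs <- g$arcs[-i, , drop = FALSE]
      arcs$tail[arcs$tail == v] <- u
      g <- phydag(setdiff(g$vertices, v), arcs, g$root, g$labels)
    }
  }
  g
}

#' Random MUL-tree
#'
#' Builds a random binary tree on `x` and then performs `dup` duplication
#' events: each picks a random non-root vertex and reattaches a fresh copy
#' of its subtree at a random position, so labels repeat. With
#' `binary = FALSE`, internal arcs are afterwards contracted with
#' probability `contract_prob` each, producing multifurcations.
#'
#' @param x Character vector of labels (distinct).
#' @param dup Number of subtree duplication events.
#' @param seed Optional integer seed.
#' @param binary Keep the tree binary?
#' @param contract_prob See [random_network()].
#' @return A `phydag` MUL-tree in which every label of `x` appears.
#' @export
random_multree <- function(x, dup = 1L, seed = NULL, binary = TRUE,
                           contract_prob = 0.25) {
  with_seed(seed, {
    g <- random_binary_tree(x)
    for (k in seq_len(dup)) {
      src <- setdiff(g$vertices, g$root)
      v <- src[[sample.int(length(src), 1L)]]
      sub <- subtree_at(g, v)
      ren <- stats::setNames(fresh_ids("c", length(sub$vertices),
                                       g$vertices), sub$vertices)
      pos <- sample.int(nrow(g$arcs) + 1L, 1L)
      new_int <- fresh_ids("i", 1L, c(g$vertices, unname(ren)))
      sub_arcs <- data.frame(tail = unname(ren[sub$arcs$tail]),
                             head = unname(ren[sub$arcs$head]),
                             key = integer(nrow(sub$arcs)),
                             stringsAsFactors = FALSE)
      sub_labels <- stats::setNames(unname(sub$labels),
                                    unname(ren[names(sub$labels)]))
      if (pos > nrow(g$arcs)) {
        g <- phydag(c(g$vertices, unname(ren), new_int),
                    rbind(g$arcs, sub_arcs,
                          data.frame(tail = new_int,
                                     head = c(g$root, ren[[sub$root]]),
                                     key = 0L, stringsAsFactors = FALSE)),
                    new_int, c(g$labels, sub_labels))
      } else {
        a <- g$arcs[pos, ]
        g <- phydag(c(g$vertices, unname(ren), new_int),
                    rbind(g$arcs[-pos, , drop = FALSE], sub_arcs,
                          data.frame(tail = c(a$tail, new_int, new_int),
                                     head = c(new_int, a$head,
                                              ren[[sub$root]]),
                                     key = 0L, stringsAsFactors = FALSE)),
                    g$root, c(g$labels, sub_labels))
      }
    }
    if (!binary) {
      repeat {
        adj <- graph_adj(g)
        cand <- which(adj$outdeg[g$arcs$head] >= 2L)
        cand <- cand[stats::runif(length(cand)) < contract_prob]
        if (!length(cand)) break
        i <- cand[[1L]]
        u <- g$arcs$tail[[i]]; v <- g$arcs$head[[i]]
        arcs <- g$arcs[-i, , drop = FALSE]
        arcs$tail[arcs$tail == v] <- u
        g <- phydag(setdiff(g$vertices, v), arcs, g$root, g$labels)
      }
    }
    g
  })
}
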