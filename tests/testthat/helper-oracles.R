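# Independent oracles and small utilities shared across the test files.
# Everything here is deliberately naive (enumeration / recursion) so that it
# can serve as a cross-check for the package's algorithms.

# Label-respecting digraph isomorphism of rooted trees by exhaustive child
# matching (exponential; fine for the small trees it is used on).
brute_iso_multree <- function(t1, t2) {
  if (length(t1$vertices) != length(t2$vertices) ||
      nrow(t1$arcs) != nrow(t2$arcs)) return(FALSE)
  a1 <- netfold:::graph_adj(t1); a2 <- netfold:::graph_adj(t2)
  perms <- function(x) {
    if (length(x) <= 1L) return(list(x))
    do.call(c, lapply(seq_along(x), function(i)
      lapply(perms(x[-i]), function(p) c(x[[i]], p))))
  }
  match_v <- function(v, w) {
    if (a1$outdeg[[v]] != a2$outdeg[[w]] ||
        a1$indeg[[v]] != a2$indeg[[w]]) return(FALSE)
    if (a1$outdeg[[v]] == 0L)
      return(identical(netfold:::g_label(t1, v), netfold:::g_label(t2, w)))
    k1 <- a1$children[[v]]
    for (p in perms(a2$children[[w]]))
      if (all(mapply(match_v, k1, p))) return(TRUE)
    FALSE
  }
  match_v(t1$root, t2$root)
}

# Network isomorphism by enumerating all bijections of internal vertices
# (leaves are pinned by their labels).
brute_iso_network <- function(n1, n2) {
  if (!setequal(unname(n1$labels), unname(n2$labels))) return(FALSE)
  if (length(n1$vertices) != length(n2$vertices) ||
      nrow(n1$arcs) != nrow(n2$arcs)) return(FALSE)
  l1 <- names(n1$labels)[order(unname(n1$labels))]
  l2 <- names(n2$labels)[order(unname(n2$labels))]
  i1 <- setdiff(n1$vertices, l1); i2 <- setdiff(n2$vertices, l2)
  if (length(i1) != length(i2)) return(FALSE)
  cnt2 <- table(paste(n2$arcs$tail, n2$arcs$head))
  perms <- function(x) {
    if (length(x) <= 1L) return(list(x))
    do.call(c, lapply(seq_along(x), function(i)
      lapply(perms(x[-i]), function(p) c(x[[i]], p))))
  }
  for (p in perms(i2)) {
    map <- stats::setNames(c(l2, p), c(l1, i1))
    cnt1 <- table(paste(map[n1$arcs$tail], map[n1$arcs$head]))
    if (length(cnt1) == length(cnt2) &&
        setequal(names(cnt1), names(cnt2)) &&
        all(cnt1[names(cnt2)] == cnt2)) return(TRUE)
  }
  FALSE
}

# Number of directed root-to-leaf paths, by dynamic programming over a
# topological order (independent of the unfolding machinery).
count_root_leaf_paths <- function(n) {
  adj <- netfold:::graph_adj(n)
  ord <- netfold:::topo_order(n, adj)
  pc <- stats::setNames(numeric(length(n$vertices)), n$vertices)
  pc[[n$root]] <- 1
  for (v in ord) for (w in adj$children[[v]]) pc[[w]] <- pc[[w]] + pc[[v]]
  sum(pc[names(n$labels)])
}

# A tree guaranteed to be displayed by the binary network `n`: keep one
# random incoming arc per reticulation and clean the selection.
displayed_tree_from <- function(n, seed) {
  set.seed(seed)
  adj <- netfold:::graph_adj(n)
  rets <- names(adj$indeg)[adj$indeg >= 2L]
  drop <- unlist(lapply(rets, function(r) {
    rows <- which(n$arcs$head == r)
    rows[-sample.int(length(rows), 1L)]
  }))
  keep_rows <- setdiff(seq_len(nrow(n$arcs)), drop)
  g <- phydag(n$vertices, n$arcs[keep_rows, , drop = FALSE], n$root, n$labels)
  keep <- netfold:::descendants_incl(g, g$root)
  netfold:::clean_to_tree(
    phydag(keep, g$arcs[g$arcs$tail %in% keep & g$arcs$head %in% keep,
                        , drop = FALSE], g$root, g$labels))
}

# Seeded policy picking a random maximal class and kept copy at every step.
random_fold_policy <- function(seed) {
  force(seed)
  env <- new.env(parent = emptyenv()); env$k <- 0L
  function(codes, cls) {
    env$k <- env$k + 1L
    set.seed(seed + env$k)
    code <- codes[[sample.int(length(codes), 1L)]]
    list(code = code, v = cls[[code]][[sample.int(length(cls[[code]]), 1L)]])
  }
}

# Random perturbations of a partition (merge / split / move one vertex).
perturb_partition <- function(p, mode, seed) {
  set.seed(seed)
  if (mode == 1L && length(p) >= 2L) {
    i <- sample.int(length(p), 2L)
    c(p[-i], list(c(p[[i[[1L]]]], p[[i[[2L]]]])))
  } else if (mode == 2L) {
    big <- which(lengths(p) >= 2L)
    if (!length(big)) return(p)
    i <- big[[sample.int(length(big), 1L)]]
    c(p[-i], list(p[[i]][1L], p[[i]][-1L]))
  } else {
    big <- which(lengths(p) >= 2L)
    if (!length(big) || length(p) < 2L) return(p)
    i <- big[[sample.int(length(big), 1L)]]
    j <- sample(setdiff(seq_along(p), i), 1L)
    v <- p[[i]][[1L]]
    p[[i]] <- setdiff(p[[i]], v)
    p[[j]] <- c(p[[j]], v)
    p
  }
}

# Exhaustively count lifts h with f o h = g and h(root) = base (uniqueness
# oracle): candidate arcs are enumerated, not assumed unique.
count_lifts_from <- function(g, f, tprime, t, base) {
  ta <- netfold:::arc_ids(t)
  tarc <- netfold:::split_arc_id(ta)
  f_img <- unname(f$amap[ta])
  arcs_p <- tprime$arcs
  ord <- netfold:::topo_order(tprime)
  by_tail <- split(seq_len(nrow(arcs_p)), factor(arcs_p$tail, tprime$vertices))
  n_sol <- 0L
  rec <- function(vmap, idx) {
    if (idx > length(ord)) { n_sol <<- n_sol + 1L; return(invisible()) }
    v <- ord[[idx]]
    rows <- by_tail[[v]]
    choices <- lapply(rows, function(i) {
      aid <- netfold:::arc_id(arcs_p$tail[[i]], arcs_p$head[[i]],
                              arcs_p$key[[i]])
      which(f_img == g$amap[[aid]] & tarc$tail == vmap[[v]])
    })
    grid_rec <- function(k, vm) {
      if (k > length(rows)) return(rec(vm, idx + 1L))
      for (c_i in choices[[k]]) {
        vm2 <- vm
        vm2[[arcs_p$head[[rows[[k]]]]]] <- tarc$head[[c_i]]
        grid_rec(k + 1L, vm2)
      }
    }
    grid_rec(1L, vmap)
  }
  vm <- stats::setNames(rep(NA_character_, length(tprime$vertices)),
                        tprime$vertices)
  vm[[tprime$root]] <- base
  rec(vm, 1L)
  n_sol
}

# Has the graph parallel arcs?
has_parallel <- function(g) anyDuplicated(g$arcs[c("tail", "head")]) > 0L
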