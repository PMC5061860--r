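# X-morphisms, folding maps, the five-property fibre-partition
# characterisation, quotients by a vertex partition, and path lifting.
#
# Morphisms are explicit data (vertex map + arc map); every theorem-level
# statement in the package is checked by verifying such certificates.

#' Construct an X-morphism
#'
#' A structure-preserving map between a (pseudo) MUL-tree and a network,
#' given as a pair of total maps: `vmap` on vertices and `amap` on arcs (arc
#' ids are `"tail|head|key"` strings as produced by the package).
#'
#' @param vmap Named character vector: domain vertex id -> codomain vertex id.
#' @param amap Named character vector: domain arc id -> codomain arc id.
#' @return An object of class `xmorphism`.
#' @export
xmorphism <- function(vmap, amap) {
  structure(list(vmap = vmap, amap = amap), class = "xmorphism")
}

#' @export
print.xmorphism <- function(x, ...) {
  cat(sprintf("<xmorphism> %d vertices, %d arcs\n",
              length(x$vmap), length(x$amap)))
  invisible(x)
}

split_arc_id <- function(a) {
  parts <- strsplit(a, "|", fixed = TRUE)
  data.frame(tail = vapply(parts, `[[`, character(1), 1L),
             head = vapply(parts, `[[`, character(1), 2L),
             key = as.integer(vapply(parts, `[[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

#' Verify that a map is an X-morphism
#'
#' Checks that `f` is total on the vertices and arcs of `t`, preserves
#' incidence (`h(f(a)) = f(h(a))` and `t(f(a)) = f(t(a))`), sends every leaf
#' labelled `x` to the leaf labelled `x` in `n`, and — when `rooted` — maps
#' root to root.
#'
#' @param f An `xmorphism`.
#' @param t The domain `phydag` (a pseudo MUL-tree).
#' @param n The codomain `phydag` (a network).
#' @param rooted Require `f(root(t)) == root(n)`?
#' @return A list with `ok` and a character vector `violations`.
#' @export
verify_x_morphism <- function(f, t, n, rooted = FALSE) {
  bad <- character(0)
  tv <- t$vertices; ta <- arc_ids(t); na <- arc_ids(n)
  miss_v <- setdiff(tv, names(f$vmap))
  if (length(miss_v))
    bad <- c(bad, paste0("vmap not defined on: ", paste(miss_v, collapse = ", ")))
  miss_a <- setdiff(ta, names(f$amap))
  if (length(miss_a))
    bad <- c(bad, paste0("amap not defined on: ", paste(miss_a, collapse = ", ")))
  bad_img_v <- setdiff(unname(f$vmap[intersect(names(f$vmap), tv)]), n$vertices)
  if (length(bad_img_v))
    bad <- c(bad, paste0("vertex images not in codomain: ",
                         paste(bad_img_v, collapse = ", ")))
  bad_img_a <- setdiff(unname(f$amap[intersect(names(f$amap), ta)]), na)
  if (length(bad_img_a))
    bad <- c(bad, paste0("arc images not in codomain: ",
                         paste(bad_img_a, collapse = ", ")))
  if (!length(bad)) {
    dom <- split_arc_id(ta)
    img <- split_arc_id(unname(f$amap[ta]))
    ok_head <- img$head == unname(f$vmap[dom$head])
    ok_tail <- img$tail == unname(f$vmap[dom$tail])
    if (!all(ok_head & ok_tail))
      bad <- c(bad, paste0("incidence violated at arcs: ",
                           paste(ta[!(ok_head & ok_tail)], collapse = ", ")))
    for (v in names(t$labels)) {
      img_v <- f$vmap[[v]]
      lab_img <- g_label(n, img_v)
      if (is.na(lab_img) || lab_img != t$labels[[v]])
        bad <- c(bad, sprintf("leaf '%s' (label %s) maps to '%s', not the leaf labelled %s",
                              v, t$labels[[v]], img_v, t$labels[[v]]))
    }
    if (rooted && f$vmap[[t$root]] != n$root)
      bad <- c(bad, sprintf("root maps to '%s', not the root", f$vmap[[t$root]]))
  }
  list(ok = length(bad) == 0L, violations = bad)
}

#' Verify that an X-morphism is a folding map
#'
#' A folding map is an X-morphism whose vertex and arc maps are surjective
#' and which has the unique-lifting property: for every arc `a` of `n` and
#' every vertex `v` of `t` with `f(v) = t(a)` there is exactly one arc of `t`
#' with tail `v` mapping to `a`. The returned report carries the lifting
#' counts for each failing `(a, v)` pair.
#'
#' @inheritParams verify_x_morphism
#' @return A list with `ok`, `violations`, and `lifting_failures` (a data
#'   frame of arc, vertex and count for every pair with count != 1).
#' @export
verify_folding_map <- function(f, t, n) {
  base <- verify_x_morphism(f, t, n, rooted = FALSE)
  bad <- base$violations
  fails <- data.frame(arc = character(), vertex = character(),
                      count = integer(), stringsAsFactors = FALSE)
  if (base$ok) {
    na <- arc_ids(n)
    if (!setequal(unname(f$vmap[t$vertices]), n$vertices))
      bad <- c(bad, "vertex map not surjective")
    if (!setequal(unname(f$amap[arc_ids(t)]), na))
      bad <- c(bad, "arc map not surjective")
    ta <- arc_ids(t)
    dom <- split_arc_id(ta)
    img <- unname(f$amap[ta])
    narcs <- split_arc_id(na)
    # count liftings: group t-arcs by (image arc, image of tail)
    lift_key <- paste(img, dom$tail, sep = "\r")
    cnt <- table(lift_key)
    for (i in seq_along(na)) {
      a <- na[[i]]
      tl <- narcs$tail[[i]]
      for (v in t$vertices[unname(f$vmap[t$vertices]) == tl]) {
        k <- paste(a, v, sep = "\r")
        m <- if (k %in% names(cnt)) as.integer(cnt[[k]]) else 0L
        if (m != 1L)
          fails <- rbind(fails, data.frame(arc = a, vertex = v, count = m,
                                           stringsAsFactors = FALSE))
      }
    }
    if (nrow(fails))
      bad <- c(bad, sprintf("unique lifting fails for %d (arc, vertex) pairs",
                            nrow(fails)))
  }
  list(ok = length(bad) == 0L, violations = bad, lifting_failures = fails)
}

# ---------------------------------------------------------------------------
# Partitions.

# p: list of character vectors (blocks). Returns block id per vertex.
block_of <- function(p, vertices) {
  out <- stats::setNames(rep(NA_integer_, length(vertices)), vertices)
  for (i in seq_along(p)) out[p[[i]]] <- i
  out
}

#' Check whether a vertex partition is the fibre partition of a folding map
#'
#' Tests the five properties that characterise when the blocks of a partition
#' of the vertices of a pseudo MUL-tree are the fibres of a folding map onto
#' some phylogenetic network: (i) the local out-isomorphism property (two
#' block-mates have child arcs matched block-wise, with multiplicity);
#' (ii) every degree-two vertex lies in a block of size at least 2 containing
#' a member whose parent is in a different block; (iii) any two block-mates
#' of a non-degree-two, non-root vertex have parents in the same block;
#' (iv) the block of a leaf labelled `x` is exactly the set of leaves
#' labelled `x`; (v) no two distinct block-mates share a parent (which is
#' what rules out parallel arcs in the quotient).
#'
#' @param t A `phydag` pseudo MUL-tree.
#' @param p A list of character vectors partitioning the vertices of `t`.
#' @return A list with `ok`, one logical per property (`loip`, `deg2_blocks`,
#'   `parent_coherence`, `leaf_blocks`, `no_shared_parent`) and a character
#'   vector `violations`.
#' @export
partition_is_fibration <- function(t, p) {
  blk <- block_of(p, t$vertices)
  if (anyNA(blk) || sum(lengths(p)) != length(t$vertices))
    stop("p is not a partition of the vertices of t")
  adj <- graph_adj(t)
  parent_of <- function(v) {
    pa <- adj$parents[[v]]
    if (length(pa)) pa[[1L]] else NA_character_
  }
  bad <- character(0)

  # (i) LOIP: multiset of child blocks equal within each block.
  loip <- TRUE
  for (b in p) {
    sigs <- vapply(b, function(v)
      paste(sort(blk[adj$children[[v]]]), collapse = ","), character(1))
    if (length(unique(sigs)) > 1L) {
      loip <- FALSE
      bad <- c(bad, paste0("LOIP fails on block {", paste(b, collapse = ","), "}"))
    }
  }
  # (ii) degree-two vertices.
  deg2 <- setdiff(names(adj$indeg)[adj$indeg == 1L & adj$outdeg == 1L], t$root)
  deg2_ok <- TRUE
  for (v in deg2) {
    b <- p[[blk[[v]]]]
    pa_v <- parent_of(v)
    others <- vapply(b, function(w) {
      pw <- parent_of(w)
      is.na(pw) || blk[[pw]] != blk[[pa_v]]
    }, logical(1))
    if (length(b) < 2L || !any(others)) {
      deg2_ok <- FALSE
      bad <- c(bad, sprintf("degree-two vertex '%s' violates the block condition", v))
    }
  }
  # (iii) parent coherence for non-degree-two, non-root vertices.
  coher_ok <- TRUE
  for (v in setdiff(t$vertices, c(t$root, deg2))) {
    if (adj$indeg[[v]] != 1L) next
    pa_v <- parent_of(v)
    for (w in p[[blk[[v]]]]) {
      pw <- parent_of(w)
      if (is.na(pw) || blk[[pw]] != blk[[pa_v]]) {
        coher_ok <- FALSE
        bad <- c(bad, sprintf("parents of '%s' and '%s' lie in different blocks", v, w))
        break
      }
    }
  }
  # (iv) leaf blocks = label classes.
  leaf_ok <- TRUE
  for (x in unique(unname(t$labels))) {
    chi <- names(t$labels)[t$labels == x]
    bs <- unique(blk[chi])
    if (length(bs) != 1L || !setequal(p[[bs[[1L]]]], chi)) {
      leaf_ok <- FALSE
      bad <- c(bad, sprintf("block of label '%s' is not exactly its leaf class", x))
    }
  }
  # (v) no two distinct block-mates share a parent.
  par_ok <- TRUE
  for (b in p) {
    pas <- vapply(b, parent_of, character(1))
    pas <- pas[!is.na(pas)]
    if (anyDuplicated(pas)) {
      par_ok <- FALSE
      bad <- c(bad, paste0("block {", paste(b, collapse = ","),
                           "} has two members sharing a parent"))
    }
  }
  list(ok = loip && deg2_ok && coher_ok && leaf_ok && par_ok,
       loip = loip, deg2_blocks = deg2_ok, parent_coherence = coher_ok,
       leaf_blocks = leaf_ok, no_shared_parent = par_ok,
       violations = bad)
}

#' Quotient of a pseudo MUL-tree by a vertex partition
#'
#' Builds the quotient DAG with one vertex per block and `m` parallel arcs
#' from block `[u]` to block `[v]` where `m` is the number of children of a
#' representative of `[u]` lying in `[v]` (checked to be
#' representative-independent; a violation raises an error naming the
#' offending blocks). Arcs within a block are ignored. A block is labelled
#' `x` when all its members are leaves labelled `x`.
#'
#' @param t A `phydag` pseudo MUL-tree.
#' @param p A list of character vectors partitioning the vertices of `t`.
#' @return A list with `raw` (the unsuppressed quotient as a `phydag`),
#'   `network` (the quotient after suppression of degree-two vertices),
#'   `projection` (the `xmorphism` from `t` onto `raw`) and `blocks` (`p`
#'   with the generated quotient vertex ids as names).
#' @export
quotient_by_partition <- function(t, p) {
  blk <- block_of(p, t$vertices)
  if (anyNA(blk) || sum(lengths(p)) != length(t$vertices))
    stop("p is not a partition of the vertices of t")
  adj <- graph_adj(t)
  qid <- paste0("q", seq_along(p))
  # child-block count vectors; must agree across members of a block
  sig <- function(v) {
    cb <- blk[adj$children[[v]]]
    tab <- table(cb)
    tab
  }
  arcs_tail <- character(0); arcs_head <- character(0); arcs_key <- integer(0)
  for (i in seq_along(p)) {
    b <- p[[i]]
    tabs <- lapply(b, sig)
    ref <- tabs[[1L]]
    for (j in seq_along(tabs)[-1L]) {
      if (!identical(sort(names(ref)), sort(names(tabs[[j]]))) ||
          !all(as.integer(ref[sort(names(ref))]) ==
               as.integer(tabs[[j]][sort(names(tabs[[j]]))])))
        stop(sprintf(paste0("arc multiplicities depend on the representative ",
                            "in block %d (vertices '%s' vs '%s'); the partition ",
                            "violates the local out-isomorphism property"),
                     i, b[[1L]], b[[j]]))
    }
    for (bn in names(ref)) {
      jb <- as.integer(bn)
      if (jb == i) next               # in-block arcs are dropped
      m <- as.integer(ref[[bn]])
      arcs_tail <- c(arcs_tail, rep(qid[[i]], m))
      arcs_head <- c(arcs_head, rep(qid[[jb]], m))
      arcs_key <- c(arcs_key, seq_len(m) - 1L)
    }
  }
  labels <- character(0)
  for (i in seq_along(p)) {
    b <- p[[i]]
    labs <- vapply(b, function(v) {
      l <- g_label(t, v)
      if (is.na(l) || adj$outdeg[[v]] > 0L) NA_character_ else l
    }, character(1))
    if (!anyNA(labs) && length(unique(labs)) == 1L) labels[qid[[i]]] <- labs[[1L]]
  }
  raw <- phydag(qid,
                data.frame(tail = arcs_tail, head = arcs_head, key = arcs_key,
                           stringsAsFactors = FALSE),
                qid[[blk[[t$root]]]], labels)
  # projection morphism t -> raw; each t-arc maps to one quotient arc, and
  # sibling arcs into the same block take distinct parallel copies.
  vmap <- stats::setNames(qid[blk[t$vertices]], t$vertices)
  ta <- arc_ids(t)
  tarc <- split_arc_id(ta)
  used <- new.env(parent = emptyenv())
  amap <- character(length(ta)); names(amap) <- ta
  for (i in seq_along(ta)) {
    bt <- blk[[tarc$tail[[i]]]]; bh <- blk[[tarc$head[[i]]]]
    if (bt == bh) { amap[[i]] <- NA_character_; next }
    k <- paste(tarc$tail[[i]], bh, sep = "\r")    # per tail vertex and block
    used[[k]] <- if (is.null(used[[k]])) 0L else used[[k]] + 1L
    amap[[i]] <- arc_id(qid[[bt]], qid[[bh]], used[[k]])
  }
  structure(list(raw = raw, network = suppress_degree_two(raw),
                 projection = xmorphism(vmap, amap[!is.na(amap)]),
                 blocks = stats::setNames(p, qid)),
            class = "quotient_result")
}

#' Lift an X-morphism through a folding map
#'
#' Given an X-morphism `g` from a pseudo MUL-tree into a network and a
#' folding map `f` from another pseudo MUL-tree onto the same network,
#' constructs top-down the unique lift `g~` with `f o g~ = g`. When `g` is
#' rooted the starting point is forced (the fibre of the root); otherwise the
#' base point defaults to the fibre member with the smallest canonical
#' subtree form (ties broken by vertex id), or can be supplied.
#'
#' @param g An `xmorphism` from `tprime` to `n`.
#' @param f A verified folding map `xmorphism` from `t` to `n`.
#' @param tprime,t,n The `phydag` objects involved.
#' @param base Optional vertex of `t` to use as the image of the root of
#'   `tprime` (must lie in the fibre of `g(root)`).
#' @return An `xmorphism` from `tprime` to `t`.
#' @export
lift_morphism <- function(g, f, tprime, t, n, base = NULL) {
  g_root <- g$vmap[[tprime$root]]
  fibre <- t$vertices[unname(f$vmap[t$vertices]) == g_root]
  if (!length(fibre)) stop("empty fibre over the image of the root; f is not a folding map")
  start <- if (!is.null(base)) {
    if (!base %in% fibre) stop("base point is not in the fibre of g(root)")
    base
  } else if (length(fibre) == 1L) {
    fibre[[1L]]
  } else {
    codes <- canonical_codes(t)
    fibre[order(codes[fibre], fibre, method = "radix")][[1L]]
  }
  adj <- graph_adj(tprime)
  ord <- topo_order(tprime, adj)
  vmap <- stats::setNames(rep(NA_character_, length(tprime$vertices)),
                          tprime$vertices)
  vmap[[tprime$root]] <- start
  ta <- arc_ids(t)
  tarc <- split_arc_id(ta)
  f_img <- unname(f$amap[ta])
  amap <- character(0)
  arcs_p <- tprime$arcs
  arcs_by_tail <- split(seq_len(nrow(arcs_p)), factor(arcs_p$tail,
                                                      tprime$vertices))
  for (v in ord) {
    for (i in arcs_by_tail[[v]]) {
      a_id <- arc_id(arcs_p$tail[[i]], arcs_p$head[[i]], arcs_p$key[[i]])
      target <- g$amap[[a_id]]
      cand <- which(f_img == target & tarc$tail == vmap[[v]])
      if (length(cand) != 1L)
        stop(sprintf("arc '%s' has %d liftings at '%s'; f is not a folding map",
                     a_id, length(cand), vmap[[v]]))
      amap[[a_id]] <- ta[[cand]]
      vmap[[arcs_p$head[[i]]]] <- tarc$head[[cand]]
    }
  }
  xmorphism(vmap, amap)
}
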