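tree_acb <- function() read_mul_newick("((a,c),b);")
tree_abc <- function() read_mul_newick("((a,b),c);")

test_that("brute-force display matches hand enumeration on the fixture", {
  n1 <- fixture_n1()
  d <- displays(n1, tree_acb())
  expect_true(isTRUE(d))
  w <- attr(d, "witness")
  expect_true(validate_graph(w, "pseudo_mul_tree")$ok)
  expect_true(multree_isomorphic(netfold:::as_multree(w), tree_acb()))
  expect_false(isTRUE(displays(n1, tree_abc())))
  tr <- random_binary_tree(letters[1:4], seed = 12)
  expect_true(isTRUE(displays(tr, tr)))
  expect_error(displays(n1, tree_acb(), max_ret = 0L), "reticulations")
})

test_that("display inside a MUL-tree finds embeddings and rejects others", {
  expect_true(displays_in_multree(fixture_m1(), tree_acb()))
  expect_false(displays_in_multree(fixture_m1(), tree_abc()))
  tr <- random_binary_tree(letters[1:4], seed = 13)
  expect_true(displays_in_multree(tr, tr))
})

test_that("the weak-display dynamic program matches the fixture traces", {
  n1 <- fixture_n1()
  expect_true(isTRUE(weakly_displays(n1, tree_acb())))
  expect_false(isTRUE(weakly_displays(n1, tree_abc())))
  # a tree weakly displays a tree exactly when they are isomorphic
  t1 <- random_binary_tree(letters[1:4], seed = 14)
  t2 <- random_binary_tree(letters[1:4], seed = 15)
  expect_true(isTRUE(weakly_displays(t1, t1)))
  expect_identical(isTRUE(weakly_displays(t1, t2)),
                   isTRUE(network_isomorphic(t1, t2)))
})

test_that("extracted reconciliations match the worked example", {
  n1 <- fixture_n1()
  rec <- reconciliation(n1, tree_acb())
  expect_identical(unname(rec$r[names(rec$r) != ""][
    vapply(names(rec$r), function(v) is.na(netfold:::g_label(tree_acb(), v)),
           logical(1))]), c("rho", "u"))
  paths <- lapply(rec$paths, function(p) netfold:::split_arc_id(p))
  lens <- sort(vapply(rec$paths, length, integer(1)))
  expect_identical(unname(lens), c(1L, 1L, 2L, 2L))   # rho->u, u->a, u->r->c, rho->v->b
  vr <- verify_reconciliation(rec, tree_acb(), n1)
  expect_true(vr$ok && vr$locally_separated)
  expect_null(reconciliation(n1, tree_abc()))
  # identity reconciliation on a tree
  tr <- random_binary_tree(letters[1:4], seed = 16)
  rid <- reconciliation(tr, tr)
  expect_true(all(vapply(rid$paths, length, integer(1)) == 1L))
  expect_true(verify_reconciliation(rid, tr, tr)$ok)
})

test_that("reconciliation verification flags broken and non-separated maps", {
  n1 <- fixture_n1()
  t <- tree_acb()
  rec <- reconciliation(n1, t)
  # truncate one path to be empty although its endpoints differ
  bad1 <- rec
  long <- names(bad1$paths)[vapply(bad1$paths, length, integer(1)) == 2L][[1L]]
  bad1$paths[[long]] <- character(0)
  expect_false(verify_reconciliation(bad1, t, n1)$ok)
  # give two sibling paths the same initial arc
  bad2 <- rec
  arcs_t <- netfold:::arc_ids(t)
  root_arcs <- arcs_t[netfold:::split_arc_id(arcs_t)$tail == t$root]
  bad2$paths[[root_arcs[[1L]]]] <- bad2$paths[[root_arcs[[2L]]]]
  vr2 <- verify_reconciliation(bad2, t, n1)
  expect_false(vr2$locally_separated)
})

test_that("weak display equals display in the unfolding, with sound witnesses", {
  for (i in 1:60) {
    nx <- 3 + i %% 4
    nw <- random_network(letters[1:nx], i %% 4, character(0), seed = 5300 + i)
    tt <- if (i %% 2 == 0 && net_properties(nw)$binary)
      displayed_tree_from(nw, 5400 + i)
    else random_binary_tree(letters[1:nx], seed = 5500 + i)
    wd <- weakly_displays(nw, tt)
    expect_identical(isTRUE(c(wd)), displays_in_multree(unfold(nw), tt))
    tab <- attr(wd, "table")
    # monotonicity of the indicator along ancestors
    adjn <- netfold:::graph_adj(nw)
    for (u in colnames(tab$tau))
      for (p in unique(adjn$parents[[u]]))
        expect_false(any(tab$tau[, u] == 1L & tab$tau[, p] == 0L))
    expect_lte(tab$updates, 4L * tab$m * tab$n * max(1L, tab$k))
    if (isTRUE(c(wd))) {
      rec <- reconciliation(nw, tt, wd)
      expect_true(verify_reconciliation(rec, tt, nw)$ok)
    }
  }
})

test_that("display implies weak display on binary instances", {
  for (i in 1:20) {
    nw <- random_network(letters[1:(3 + i %% 3)], 1 + i %% 3, c("binary"),
                         seed = 5800 + i)
    tt <- displayed_tree_from(nw, 5900 + i)
    expect_true(isTRUE(displays(nw, tt)))
    expect_true(isTRUE(weakly_displays(nw, tt)))
  }
})

test_that("a hand-built locally separated reconciliation certifies weak display", {
  # embed the tree ((a,c),b) into N1 by hand and verify both directions
  n1 <- fixture_n1()
  t <- tree_acb()
  adjt <- netfold:::graph_adj(t)
  cherry <- adjt$children[[t$root]][[which(vapply(
    adjt$children[[t$root]], function(v) adjt$outdeg[[v]] > 0L, logical(1)))]]
  leaf_of <- function(lb) names(t$labels)[t$labels == lb]
  r <- stats::setNames(rep(NA_character_, 5L), t$vertices)
  r[[t$root]] <- "rho"; r[[cherry]] <- "u"
  r[[leaf_of("a")]] <- "a"; r[[leaf_of("b")]] <- "b"; r[[leaf_of("c")]] <- "c"
  paths <- list()
  paths[[netfold:::arc_id(t$root, cherry, 0L)]] <- "rho|u|0"
  paths[[netfold:::arc_id(t$root, leaf_of("b"), 0L)]] <- c("rho|v|0", "v|b|0")
  paths[[netfold:::arc_id(cherry, leaf_of("a"), 0L)]] <- "u|a|0"
  paths[[netfold:::arc_id(cherry, leaf_of("c"), 0L)]] <- c("u|r|0", "r|c|0")
  rec <- structure(list(r = r, paths = paths), class = "reconciliation")
  expect_true(verify_reconciliation(rec, t, n1)$ok)
  expect_true(isTRUE(weakly_displays(n1, t)))
})

test_that("the HangLeaves gadget adds exactly the prescribed structure", {
  n1 <- fixture_n1()
  t <- tree_acb()
  hl <- hang_leaves(n1, t, "u")
  expect_identical(length(hl$network$vertices), length(n1$vertices) + 5L)
  expect_identical(nrow(hl$network$arcs), nrow(n1$arcs) + 6L)
  expect_identical(length(hl$tree$vertices), length(t$vertices) + 4L)
  expect_identical(nrow(hl$tree$arcs), nrow(t$arcs) + 4L)
  expect_identical(vertex_class(hl$network, "q_u"), "reticulation")
  expect_identical(vertex_class(hl$network, "p_u"), "internal_tree")
  expect_identical(vertex_class(hl$network, "rho_u"), "root")
  # two applications with distinct vertices use disjoint fresh labels
  hl2 <- hang_leaves(hl$network, hl$tree, "v")
  expect_identical(length(intersect(hl$new_labels, hl2$new_labels)), 0L)
  expect_true(validate_graph(hl2$network, "phylo_network")$ok)
  expect_true(validate_graph(hl2$tree, "phylo_network")$ok)
  expect_error(hang_leaves(hl$network, hl$tree, "v", tag = "u"), "collide")
})

test_that("the stable-instance reduction matches the fixture walkthrough", {
  n1 <- fixture_n1()
  si <- stable_instance(n1, tree_acb())
  expect_identical(length(si$network$labels), 9L)    # 3 + 2 gadgets + 1 gadget
  p <- net_properties(si$network)
  expect_true(p$binary && p$compressed && p$tree_sibling)
  expect_true(is_stable(si$network)$stable_direct)
  expect_true(isTRUE(displays(si$network, si$tree)))
  si2 <- stable_instance(n1, tree_abc())
  expect_false(isTRUE(displays(si2$network, si2$tree)))
  expect_false(isTRUE(displays(n1, tree_abc())))
})
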