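test_that("X-morphism verification checks incidence, labels and the root", {
  n1 <- fixture_n1()
  ur <- unfold_star(n1)
  expect_true(verify_x_morphism(ur$fstar, ur$ustar, n1, rooted = TRUE)$ok)
  tr <- random_binary_tree(letters[1:4], seed = 8)
  idm <- xmorphism(stats::setNames(tr$vertices, tr$vertices),
                   stats::setNames(netfold:::arc_ids(tr),
                                   netfold:::arc_ids(tr)))
  expect_true(verify_x_morphism(idm, tr, tr, rooted = TRUE)$ok)
  # perturb one arc image: incidence must fail
  bad <- ur$fstar
  bad$amap[[1L]] <- netfold:::arc_ids(n1)[[
    which(netfold:::arc_ids(n1) != unname(bad$amap[[1L]]))[[1L]]]]
  expect_false(verify_x_morphism(bad, ur$ustar, n1)$ok)
})

test_that("folding-map verification demands surjectivity and unique lifts", {
  n1 <- fixture_n1()
  ur <- unfold_star(n1)
  expect_true(verify_folding_map(ur$fstar, ur$ustar, n1)$ok)
  tr <- random_binary_tree(letters[1:4], seed = 9)
  idm <- xmorphism(stats::setNames(tr$vertices, tr$vertices),
                   stats::setNames(netfold:::arc_ids(tr),
                                   netfold:::arc_ids(tr)))
  expect_true(verify_folding_map(idm, tr, tr)$ok)
  # collapsing M2's two cherries onto the tree (a,b) is not a folding map:
  # the root keeps two arcs onto the collapsed cherry root, so lifting the
  # single root arc of the codomain is not unique
  m2 <- fixture_m2()
  a2 <- netfold:::graph_adj(m2)
  small <- read_mul_newick("(a,b);")
  sa <- netfold:::graph_adj(small)
  cherries <- a2$children[[m2$root]]
  vmap <- stats::setNames(rep(NA_character_, 7L), m2$vertices)
  vmap[[m2$root]] <- small$root
  leaf_of <- function(lb) names(small$labels)[small$labels == lb]
  amap <- character(0)
  for (ch in cherries) {
    vmap[[ch]] <- small$root
    amap[[netfold:::arc_id(m2$root, ch, 0L)]] <- NA_character_
    for (lf in a2$children[[ch]]) {
      vmap[[lf]] <- leaf_of(m2$labels[[lf]])
      amap[[netfold:::arc_id(ch, lf, 0L)]] <-
        netfold:::arc_id(small$root, leaf_of(m2$labels[[lf]]), 0L)
    }
  }
  # the root arcs of m2 have nowhere to go (root maps onto root); map them to
  # an arbitrary arc so the morphism is total, then expect failure
  for (ch in cherries)
    amap[[netfold:::arc_id(m2$root, ch, 0L)]] <-
      netfold:::arc_id(small$root, leaf_of("a"), 0L)
  f <- xmorphism(vmap, amap)
  expect_false(verify_folding_map(f, m2, small)$ok)
})

test_that("the five-property partition test matches the fixtures", {
  f1 <- fold(fixture_m1())
  expect_true(partition_is_fibration(f1$guide, unname(f1$partition))$ok)
  f2 <- fold(fixture_m2())
  r2 <- partition_is_fibration(f2$guide, unname(f2$partition))
  expect_false(r2$ok)
  expect_false(r2$no_shared_parent)   # the two subdivision vertices under the root
  tr <- random_binary_tree(letters[1:4], seed = 10)
  expect_true(partition_is_fibration(tr, lapply(tr$vertices, identity))$ok)
})

test_that("partition validity is equivalent to a verified quotient", {
  n_true <- 0L; n_false <- 0L
  for (i in 1:40) {
    mt <- random_multree(letters[1:(2 + i %% 4)], i %% 4, seed = 4100 + i,
                         binary = i %% 2 == 0)
    ft <- fold(mt)
    plain <- setdiff(mt$vertices, mt$root)
    codes <- canonical_codes(mt)
    cases <- list(list(ft$guide, unname(ft$partition)),
                  list(mt, c(list(mt$root), unname(split(plain, codes[plain])))),
                  list(ft$guide,
                       perturb_partition(unname(ft$partition), 1L + i %% 3L, i)))
    for (cs in cases) {
      lhs <- partition_is_fibration(cs[[1L]], cs[[2L]])$ok
      q <- tryCatch(quotient_by_partition(cs[[1L]], cs[[2L]]),
                    error = function(e) NULL)
      rhs <- !is.null(q) &&
        validate_graph(q$raw, "phylo_network")$ok &&
        verify_folding_map(q$projection, cs[[1L]], q$raw)$ok
      expect_identical(lhs, rhs)
      if (lhs) n_true <- n_true + 1L else n_false <- n_false + 1L
    }
  }
  expect_gte(n_true, 10L)      # both directions genuinely exercised
  expect_gte(n_false, 10L)
})

test_that("quotients reproduce the folds and the discrete identity", {
  f1 <- fold(fixture_m1())
  q1 <- quotient_by_partition(f1$guide, unname(f1$partition))
  expect_true(isTRUE(network_isomorphic(q1$network, fixture_n1())))
  tr <- random_binary_tree(letters[1:4], seed = 11)
  qd <- quotient_by_partition(tr, lapply(tr$vertices, identity))
  expect_true(isTRUE(network_isomorphic(qd$network, tr)))
  f2 <- fold(fixture_m2())
  q2 <- quotient_by_partition(f2$guide, unname(f2$partition))
  expect_true(has_parallel(q2$raw))
})

test_that("lifting along a folding map composes exactly and is unique", {
  n1 <- fixture_n1()
  ur <- unfold_star(n1)
  self <- lift_morphism(ur$fstar, ur$fstar, ur$ustar, ur$ustar, n1)
  expect_identical(unname(self$vmap[ur$ustar$vertices]), ur$ustar$vertices)

  checked <- 0L
  for (i in 1:60) {
    nw <- random_network(letters[1:3], 1 + i %% 2, c("binary"),
                         seed = 4500 + i)
    tt <- displayed_tree_from(nw, 4600 + i)
    wd <- weakly_displays(nw, tt)
    if (!isTRUE(c(wd))) next
    rec <- reconciliation(nw, tt, wd)
    rm <- reconciliation_morphism(rec, tt, nw)
    expect_true(verify_x_morphism(rm$morphism, rm$tstar, nw,
                                  rooted = rm$morphism$vmap[[rm$tstar$root]] ==
                                    nw$root)$ok)
    ur2 <- unfold_star(nw)
    lf <- lift_morphism(rm$morphism, ur2$fstar, rm$tstar, ur2$ustar, nw)
    comp_v <- ur2$fstar$vmap[unname(lf$vmap[rm$tstar$vertices])]
    expect_identical(unname(comp_v),
                     unname(rm$morphism$vmap[rm$tstar$vertices]))
    comp_a <- ur2$fstar$amap[unname(lf$amap[names(rm$morphism$amap)])]
    expect_identical(unname(comp_a), unname(rm$morphism$amap))
    if (length(rm$tstar$vertices) <= 10L) {
      expect_identical(
        count_lifts_from(rm$morphism, ur2$fstar, rm$tstar, ur2$ustar,
                         lf$vmap[[rm$tstar$root]]), 1L)
      if (rm$morphism$vmap[[rm$tstar$root]] == nw$root)
        expect_identical(lf$vmap[[rm$tstar$root]], ur2$ustar$root)
    }
    checked <- checked + 1L
    if (checked >= 8L) break
  }
  expect_gte(checked, 3L)
})

test_that("a folding map into a network identifies its domain with the unfolding", {
  for (i in 1:12) {
    mt <- random_multree(letters[1:(2 + i %% 3)], 1 + i %% 3, seed = 4900 + i)
    ft <- fold(mt)
    q <- quotient_by_partition(ft$guide, unname(ft$partition))
    if (!validate_graph(q$raw, "phylo_network")$ok) next
    ur <- unfold_star(q$raw)
    lf <- lift_morphism(q$projection, ur$fstar, ft$guide, ur$ustar, q$raw)
    expect_false(anyDuplicated(unname(lf$vmap)) > 0)
    expect_identical(length(lf$vmap), length(ur$ustar$vertices))
    expect_true(multree_isomorphic(ft$guide, ur$ustar))
  }
})
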