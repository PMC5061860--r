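test_that("canonical codes follow the leaf/degree-two/internal grammar", {
  leaf <- phydag("a", NULL, "a", c(a = "a"))
  expect_identical(canonical_form(leaf), "L(a)")
  expect_identical(canonical_form(fixture_m3()), "I(L(a),L(a))")
  m1 <- fixture_m1(); m2 <- fixture_m2()
  a1 <- netfold:::graph_adj(m1)
  kids1 <- a1$children[[m1$root]]
  codes1 <- canonical_codes(m1)
  expect_false(codes1[[kids1[[1L]]]] == codes1[[kids1[[2L]]]])
  a2 <- netfold:::graph_adj(m2)
  kids2 <- a2$children[[m2$root]]
  codes2 <- canonical_codes(m2)
  expect_identical(codes2[[kids2[[1L]]]], codes2[[kids2[[2L]]]])
})

test_that("pseudo trees with different subdivision patterns differ", {
  path <- phydag(c("r", "d", "a"),
                 data.frame(tail = c("r", "d"), head = c("d", "a")),
                 "r", c(a = "a"))
  bare <- phydag(c("r", "a"), data.frame(tail = "r", head = "a"),
                 "r", c(a = "a"))
  expect_identical(canonical_form(path), "I(D(L(a)))")
  expect_identical(canonical_form(bare), "I(L(a))")
  expect_false(multree_isomorphic(path, bare))
})

test_that("MUL-tree isomorphism agrees with brute-force matching", {
  expect_true(multree_isomorphic(fixture_m1(), read_mul_newick("((c,b),(c,a));")))
  expect_false(multree_isomorphic(fixture_m1(), fixture_m2()))
  set.seed(11)
  for (i in 1:80) {
    x1 <- letters[1:sample(2:3, 1)]
    t1 <- random_multree(x1, sample(0:2, 1), seed = 500 + i)
    t2 <- if (i %% 3 == 0) {
      # reshuffle: rebuild t1 with renamed vertices and permuted arc rows
      map <- stats::setNames(paste0("w", seq_along(t1$vertices)), t1$vertices)
      rows <- sample(nrow(t1$arcs))
      phydag(unname(map[t1$vertices]),
             data.frame(tail = unname(map[t1$arcs$tail[rows]]),
                        head = unname(map[t1$arcs$head[rows]]),
                        key = t1$arcs$key[rows]),
             unname(map[[t1$root]]),
             stats::setNames(unname(t1$labels), unname(map[names(t1$labels)])))
    } else random_multree(x1, sample(0:2, 1), seed = 900 + i)
    if (length(t1$vertices) > 9 || length(t2$vertices) > 9) next
    expect_identical(multree_isomorphic(t1, t2), brute_iso_multree(t1, t2))
  }
})

test_that("network isomorphism agrees with brute-force bijection search", {
  n1 <- fixture_n1()
  ren <- stats::setNames(c("R", "U", "V", "X", "a", "b", "c"), n1$vertices)
  n1b <- phydag(unname(ren[n1$vertices]),
                data.frame(tail = unname(ren[n1$arcs$tail]),
                           head = unname(ren[n1$arcs$head]),
                           key = n1$arcs$key),
                unname(ren[[n1$root]]), n1$labels)
  r <- network_isomorphic(n1, n1b)
  expect_true(isTRUE(r))
  w <- attr(r, "witness")
  expect_identical(unname(w[n1$root]), "R")

  r2 <- network_isomorphic(n1, fixture_n2())
  expect_false(isTRUE(r2))
  expect_identical(attr(r2, "reason"), "label_sets")

  # swapping the labels of N2's leaves gives an isomorphic network
  n2 <- fixture_n2()
  n2s <- phydag(n2$vertices, n2$arcs, n2$root, c(a = "b", b = "a"))
  expect_true(isTRUE(network_isomorphic(n2, n2s)))
  expect_true(brute_iso_network(n2, n2s))

  for (i in 1:40) {
    a <- random_network(letters[1:3], i %% 2, character(0), seed = 700 + i)
    b <- if (i %% 3 == 0) a else
      random_network(letters[1:3], i %% 2, character(0), seed = 800 + i)
    if (length(a$vertices) > 9 || length(b$vertices) > 9) next
    expect_identical(isTRUE(network_isomorphic(a, b)), brute_iso_network(a, b))
  }
})

test_that("canonical forms are invariant under child order and vertex ids", {
  for (i in 1:25) {
    t1 <- random_multree(letters[1:(2 + i %% 4)], 1 + i %% 3, seed = 1200 + i)
    map <- stats::setNames(paste0("z", seq_along(t1$vertices)), t1$vertices)
    rows <- rev(seq_len(nrow(t1$arcs)))
    t2 <- phydag(rev(unname(map[t1$vertices])),
                 data.frame(tail = unname(map[t1$arcs$tail[rows]]),
                            head = unname(map[t1$arcs$head[rows]]),
                            key = t1$arcs$key[rows]),
                 unname(map[[t1$root]]),
                 stats::setNames(unname(t1$labels), unname(map[names(t1$labels)])))
    expect_identical(canonical_form(t1), canonical_form(t2))
  }
})
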