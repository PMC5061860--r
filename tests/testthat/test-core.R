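test_that("validation accepts the fixtures and reports degenerate inputs", {
  expect_true(validate_graph(fixture_n1(), "phylo_network")$ok)
  expect_true(validate_graph(fixture_n2(), "phylo_network")$ok)
  expect_true(validate_graph(fixture_m1(), "mul_tree")$ok)
  # repeated labels are legal in MUL-trees, even a single-label cherry
  expect_true(validate_graph(fixture_m3(), "mul_tree")$ok)

  two <- phydag(c("r", "a"), data.frame(tail = "r", head = "a"),
                "r", c(a = "a"))
  rep2 <- validate_graph(two, "x_network")
  expect_false(rep2$ok)
  expect_true(any(grepl("outdegree < 2", rep2$violations)))

  deg2 <- phydag(c("r", "m", "a", "b"),
                 data.frame(tail = c("r", "m", "r"), head = c("m", "a", "b")),
                 "r", c(a = "a", b = "b"))
  expect_false(validate_graph(deg2, "x_network")$ok)
  expect_true(validate_graph(deg2, "pseudo_mul_tree")$ok)
  expect_false(validate_graph(deg2, "mul_tree")$ok)
})

test_that("vertex classification matches in/out-degrees", {
  n1 <- fixture_n1()
  expect_identical(vertex_class(n1, "r"), "reticulation")
  expect_identical(vertex_class(n1, "rho"), "root")
  expect_identical(vertex_class(n1, "c"), "leaf")
  expect_identical(vertex_class(n1, "u"), "internal_tree")
  expect_error(vertex_class(n1, "nope"), "not in graph")
  # classes partition the vertices of a valid network
  for (s in 1:20) {
    nw <- random_network(letters[1:4], s %% 3, character(0), seed = 100 + s)
    cls <- vapply(nw$vertices, function(v) vertex_class(nw, v), character(1))
    expect_true(all(cls %in% c("root", "reticulation", "internal_tree", "leaf")))
    expect_identical(sum(cls == "root"), 1L)
  }
})

test_that("property flags match the definitions on the fixtures", {
  p1 <- net_properties(fixture_n1())
  expect_true(p1$binary && p1$compressed && p1$tree_child && p1$tree_sibling)
  expect_false(p1$has_parallel_arcs)
  p2 <- net_properties(fixture_n2())
  expect_true(p2$binary && p2$compressed)
  expect_false(p2$tree_sibling)   # both siblings of each reticulation reticulate
  tr <- random_binary_tree(letters[1:5], seed = 1)
  pt <- net_properties(tr)
  expect_true(pt$is_tree && pt$compressed && pt$tree_child && pt$tree_sibling)
})

test_that("property implications hold on random networks", {
  for (s in 1:120) {
    nw <- random_network(letters[1:(3 + s %% 4)], s %% 5, character(0),
                         seed = 2000 + s,
                         contract_prob = 0.3, extra_parent_prob = 0.3)
    p <- net_properties(nw)
    if (p$binary) expect_true(p$semi_resolved)
    if (p$tree_child) expect_true(p$tree_sibling)
    if (p$is_tree) expect_true(p$compressed && p$tree_child && p$tree_sibling)
  }
})

test_that("degree-two suppression removes chains and creates parallel arcs", {
  chain <- phydag(c("r", "m", "a", "b"),
                  data.frame(tail = c("r", "m", "r"), head = c("m", "a", "b")),
                  "r", c(a = "a", b = "b"))
  s <- suppress_degree_two(chain)
  expect_setequal(s$vertices, c("r", "a", "b"))
  expect_identical(sort(netfold:::arc_ids(s)), sort(c("r|a|0", "r|b|0")))

  n1 <- fixture_n1()
  expect_identical(suppress_degree_two(n1), n1)

  diamond <- phydag(c("r", "p", "q", "x", "y"),
                    data.frame(tail = c("r", "r", "p", "q", "x"),
                               head = c("p", "q", "x", "x", "y")),
                    "r", c(y = "y"))
  d <- suppress_degree_two(diamond)
  expect_setequal(d$vertices, c("r", "x", "y"))
  expect_identical(sum(d$arcs$tail == "r" & d$arcs$head == "x"), 2L)

  # leaves and labels survive suppression on random pseudo trees
  for (s in 1:25) {
    nw <- random_network(letters[1:4], 1 + s %% 3, character(0), seed = 300 + s)
    us <- unfold_star(nw)$ustar
    sup <- suppress_degree_two(us)
    adj <- netfold:::graph_adj(sup)
    expect_false(any(adj$indeg == 1L & adj$outdeg == 1L))
    expect_identical(sort(unname(sup$labels)), sort(unname(us$labels)))
  }
})

test_that("suppression is confluent (order of elimination is irrelevant)", {
  # eliminate degree-two vertices one at a time, in two opposite orders
  one_at_a_time <- function(g, from_last) {
    repeat {
      adj <- netfold:::graph_adj(g)
      supp <- setdiff(names(adj$indeg)[adj$indeg == 1L & adj$outdeg == 1L],
                      g$root)
      if (!length(supp)) return(g)
      v <- if (from_last) supp[[length(supp)]] else supp[[1L]]
      p <- adj$parents[[v]][[1L]]; c_ <- adj$children[[v]][[1L]]
      keep <- !(g$arcs$head == v | g$arcs$tail == v)
      key <- sum(g$arcs$tail == p & g$arcs$head == c_)
      g <- phydag(setdiff(g$vertices, v),
                  rbind(g$arcs[keep, , drop = FALSE],
                        data.frame(tail = p, head = c_, key = key,
                                   stringsAsFactors = FALSE)),
                  g$root, g$labels)
    }
  }
  for (s in 1:10) {
    nw <- random_network(letters[1:4], 1 + s %% 3, character(0), seed = 400 + s)
    us <- unfold_star(nw)$ustar
    a <- one_at_a_time(us, FALSE)
    b <- one_at_a_time(us, TRUE)
    d <- suppress_degree_two(us)
    expect_true(multree_isomorphic(a, b))
    expect_true(multree_isomorphic(a, d))
  }
})

test_that("subtrees and restrictions work as on the fixtures", {
  m1 <- fixture_m1()
  adj <- netfold:::graph_adj(m1)
  cherry_ac <- adj$children[[m1$root]][[
    which(vapply(adj$children[[m1$root]], function(v)
      "a" %in% m1$labels[netfold:::descendants_incl(m1, v)], logical(1)))]]
  sub <- subtree_at(m1, cherry_ac)
  expect_identical(length(sub$vertices), 3L)
  expect_setequal(unname(sub$labels), c("a", "c"))
  # subtree of a subtree equals direct subtree
  leafv <- names(m1$labels)[[1L]]
  expect_identical(canonical_form(subtree_at(sub, leafv)),
                   canonical_form(subtree_at(m1, leafv)))
  expect_error(subtree_at(m1, m1$root), "non-root")

  n1 <- fixture_n1()
  expect_true(isTRUE(network_isomorphic(restrict_below(n1, "rho"), n1)))
  ru <- restrict_below(n1, "u")
  expect_identical(canonical_form(ru), "I(L(a),L(c))")   # r was suppressed
  ra <- restrict_below(n1, "a")
  expect_identical(length(ra$vertices), 1L)
  expect_error(restrict_below(n1, "r"), "reticulation")
})
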