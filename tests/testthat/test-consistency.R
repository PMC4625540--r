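fx <- toy_fixtures()

test_that("violations report the constraint definitions", {
  g <- fx$chain$graph
  p <- fx$chain$profile
  expect_equal(nrow(violations(g, p, c(A = 1L, B = 1L), "WP")), 0L)
  v <- violations(g, p, c(A = 0L, B = 1L), "WP")
  expect_identical(v$node, c("A", "B"))
  expect_identical(v$constraint, c("C1", "C2"))
  expect_error(violations(g, p, c(A = 1L), "WP"), "not total")

  # C3 only under SP/FSP: single + influence forbids a 0 target
  g2 <- interaction_graph(data.frame(source = "B", target = "D", sign = "+"))
  p2 <- experimental_profile(inputs = "B")
  lab <- c(B = 1L, D = 0L)
  expect_equal(nrow(violations(g2, p2, lab, "WP")), 0L)
  v3 <- violations(g2, p2, lab, "SP")
  expect_identical(v3$node, "D")
  expect_identical(v3$constraint, "C3")

  # two opposing nonzero influences justify a 0
  g3 <- interaction_graph(data.frame(
    source = c("P", "Q"), target = c("D", "D"), sign = c("+", "-")
  ))
  p3 <- experimental_profile(inputs = c("P", "Q"))
  expect_equal(nrow(violations(g3, p3, c(D = 0L, P = 1L, Q = 1L), "SP")), 0L)
  # same-direction influences do not
  v4 <- violations(g3, p3, c(D = 0L, P = 1L, Q = -1L), "SP")
  expect_identical(v4$constraint, "C3")
})

test_that("opposite-sign parallel edges from one source can justify a 0 (C3)", {
  # unsigned edge encoded as two parallels: the pair counts as two distinct edges
  g <- interaction_graph(data.frame(
    source = c("P", "P"), target = c("D", "D"), sign = c("+", "-")
  ))
  p <- experimental_profile(inputs = "P")
  expect_equal(nrow(violations(g, p, c(D = 0L, P = 1L), "SP")), 0L)
  expect_true(exists_labeling(g, p, "SP", pinned = c(D = 0L, P = 1L)))
})

test_that("foundedness fixpoint excludes self-justifying loops", {
  g <- fx$positive_loop$graph # A->B, B<->C, C->D, all +
  expect_setequal(founded_nodes(g, c(A = 0L, B = 1L, C = 1L, D = 1L), "A"), "A")
  expect_setequal(founded_nodes(g, c(A = 1L, B = 1L, C = 1L, D = 1L), "A"),
                  c("A", "B", "C", "D"))
  # an input is founded regardless of label
  expect_true("A" %in% founded_nodes(g, c(A = -1L, B = 0L, C = 0L, D = 0L), "A"))
  # monotone in the input set
  f1 <- founded_nodes(g, c(A = 0L, B = 1L, C = 1L, D = 1L), "A")
  f2 <- founded_nodes(g, c(A = 0L, B = 1L, C = 1L, D = 1L), c("A", "B"))
  expect_true(all(f1 %in% f2))
})

test_that("global consistency across the fixture suite", {
  for (n in c("WP", "SP", "FWP", "FSP")) {
    expect_true(is_consistent(fx$chain$graph, fx$chain$profile, n))
  }
  # negative two-cycle: locally consistent per node, globally inconsistent
  expect_false(is_consistent(fx$inconsistent_pair$graph, fx$inconsistent_pair$profile, "WP"))
  # positive loop: SP-consistent via self-justification, FSP rejects it
  expect_true(is_consistent(fx$positive_loop$graph, fx$positive_loop$profile, "SP"))
  expect_false(is_consistent(fx$positive_loop$graph, fx$positive_loop$profile, "FSP"))
  expect_false(is_consistent(fx$positive_loop$graph, fx$positive_loop$profile, "FWP"))
})

test_that("enumeration is exact, deduplicated and lexicographic", {
  labs <- enumerate_labelings(fx$chain$graph, fx$chain$profile, "WP")
  expect_length(labs, 1L)
  expect_identical(labs[[1]], c(A = 1L, B = 1L))

  # the self-justifying loop admits exactly one SP labeling
  labs_sp <- enumerate_labelings(fx$positive_loop$graph, fx$positive_loop$profile, "SP")
  expect_length(labs_sp, 1L)
  expect_identical(labs_sp[[1]], c(A = 0L, B = 1L, C = 1L, D = 1L))
  # under WP the same single labeling survives: C2 still forces B = C = +
  labs_wp <- enumerate_labelings(fx$positive_loop$graph, fx$positive_loop$profile, "WP")
  expect_length(labs_wp, 1L)
  expect_identical(labs_wp[[1]], labs_sp[[1]])

  # order: lexicographic over sorted node ids, value order + < 0 < -
  labs_fb <- enumerate_labelings(fx$feedback$graph, fx$feedback$profile, "WP")
  keys <- vapply(labs_fb, labeling_key, character(1))
  expect_false(is.unsorted(keys))
  expect_equal(anyDuplicated(keys), 0L)
  expect_error(
    enumerate_labelings(fx$feedback$graph, fx$feedback$profile, "WP", limit = 3),
    class = "sc_limit_error"
  )
})

test_that("pinned satisfiability queries match enumeration", {
  g <- fx$positive_loop$graph
  p <- fx$positive_loop$profile
  expect_false(exists_labeling(g, p, "SP", pinned = c(B = 0L)))
  expect_false(exists_labeling(g, p, "WP", pinned = c(B = 0L))) # C2 at C forces B = +
  expect_true(exists_labeling(g, p, "WP", pinned = c(B = 1L)))
  expect_true(exists_labeling(g, p, "SP", pinned = NULL))
  expect_error(exists_labeling(g, p, "SP", pinned = c(Z = 1L)), "not in graph")
})

test_that("unmeasured predecessor-free non-inputs are forced to 0", {
  g <- interaction_graph(
    data.frame(source = "A", target = "B", sign = "+"), nodes = "L"
  )
  p <- experimental_profile(c(A = "+", B = "+"), inputs = "A")
  pm <- predict_labels(g, p, "WP")
  expect_identical(unname(pm[["L"]]), "0")
  # and an isolated unmeasured input remains free
  p2 <- experimental_profile(c(A = "+", B = "+"), inputs = c("A", "L"))
  expect_identical(unname(predict_labels(g, p2, "WP")[["L"]]), "no")
})

test_that("consistency survives adding an isolated unmeasured node", {
  for (nm in c("chain", "positive_loop", "feedback")) {
    g <- fx[[nm]]$graph
    p <- fx[[nm]]$profile
    g2 <- interaction_graph(g$edges, nodes = c(g$nodes, "zz_isolated"))
    for (notion in c("WP", "SP", "FWP", "FSP")) {
      expect_identical(
        is_consistent(g2, p, notion), is_consistent(g, p, notion),
        info = paste(nm, notion)
      )
    }
  }
})

test_that("labeling sets nest with the notions on random instances", {
  keyset <- function(g, p, n) {
    sort(vapply(enumerate_labelings(g, p, n), labeling_key, character(1)))
  }
  for (seed in 1:25) {
    inst <- random_test_instance(seed, n_max = 6L)
    k <- lapply(c(WP = "WP", SP = "SP", FWP = "FWP", FSP = "FSP"),
                function(n) keyset(inst$graph, inst$profile, n))
    expect_true(all(k$SP %in% k$WP), info = seed)
    expect_true(all(k$FWP %in% k$WP), info = seed)
    expect_true(all(k$FSP %in% k$SP), info = seed)
    expect_true(all(k$FSP %in% k$FWP), info = seed)
  }
})

test_that("search engine agrees with the brute-force oracle", {
  for (seed in 1:80) {
    inst <- random_test_instance(seed)
    L <- brute_labelings(inst$graph, inst$profile, inst$notion)
    labs <- enumerate_labelings(inst$graph, inst$profile, inst$notion)
    expect_equal(length(labs), nrow(L), info = seed)
    expect_identical(is_consistent(inst$graph, inst$profile, inst$notion),
                     nrow(L) > 0L, info = seed)
    if (nrow(L)) {
      got <- sort(vapply(labs, labeling_key, character(1)))
      want <- sort(apply(L[, inst$graph$nodes, drop = FALSE], 1L, labeling_key))
      expect_identical(got, unname(want), info = seed)
    }
  }
})
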