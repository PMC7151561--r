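path3 <- net_from_adj(adj_matrix(3, rbind(c(1, 2), c(2, 3))))

test_that("hand-derived centralities on canonical small graphs", {
  # path a-b-c: centre carries the single crossing pair, ends none
  expect_equal(as.numeric(betweenness_centrality(path3)),
               c(0, 1, 0), ignore_attr = TRUE)
  expect_equal(as.numeric(closeness_centrality(path3)),
               c(2 / 3, 1, 2 / 3), ignore_attr = TRUE)
  expect_equal(as.numeric(degree_centrality(path3)), c(1, 2, 1),
               ignore_attr = TRUE)

  # triangle: no intermediate vertices anywhere
  tri <- net_from_adj(adj_matrix(3, rbind(c(1, 2), c(2, 3), c(1, 3))))
  expect_true(all(betweenness_centrality(tri) == 0))

  # star with 4 leaves: centre carries all C(4,2) = 6 leaf pairs
  star <- net_from_adj(adj_matrix(5, cbind(1, 2:5)))
  expect_equal(as.numeric(betweenness_centrality(star)[["n01"]]), 6)
  expect_equal(as.numeric(degree_centrality(star)[["n01"]]), 4)

  # complete graph: everyone at distance 1, closeness 1
  k5 <- net_from_adj(adj_matrix(5, t(utils::combn(5, 2))))
  expect_true(all(abs(closeness_centrality(k5) - 1) < 1e-12))

  # two disjoint edges: component-scaled closeness (1/1) * (1/3)
  two <- net_from_adj(adj_matrix(4, rbind(c(1, 2), c(3, 4))))
  expect_true(all(abs(closeness_centrality(two) - 1 / 3) < 1e-12))
})

test_that("handshake lemma and report summary hold on random graphs", {
  withr::with_seed(42, {
    for (i in 1:5) {
      adj <- rand_adj(10, 0.3)
      net <- net_from_adj(adj)
      expect_equal(sum(degree_centrality(net)), 2 * nrow(net$edges))
      report <- centrality_report(net)
      smry <- centrality_summary(report)
      expect_equal(smry$mean[smry$measure == "degree"], mean(report$degree))
      expect_equal(smry$median[smry$measure == "closeness"],
                   median(report$closeness))
      expect_true(all(report$closeness >= 0 & report$closeness <= 1))
      expect_true(all(report$betweenness >= 0))
    }
  })
})

test_that("betweenness and closeness match the path-enumeration oracle", {
  withr::with_seed(7, {
    for (i in 1:10) expect_centrality_matches_oracle(rand_adj(8, 0.35))
  })
})

test_that("tree betweenness equals the crossing-pair count oracle", {
  withr::with_seed(11, {
    for (i in 1:5) {
      n <- 9
      # random tree: attach each node to a uniformly chosen predecessor
      edges <- cbind(2:n, vapply(2:n, function(v) sample(v - 1, 1), 1))
      adj <- adj_matrix(n, edges)
      net <- net_from_adj(adj)
      expect_equal(as.numeric(betweenness_centrality(net)[rownames(adj)]),
                   as.numeric(oracle_tree_betweenness(adj)),
                   tolerance = 1e-10)
    }
  })
})

test_that("key-node selection applies strict thresholds deterministically", {
  rep <- data.frame(id = c("a", "b", "c", "d"), degree = c(10, 6, 6, 2))
  # mean = 6: strictly-greater excludes the ties at the mean
  expect_identical(select_key_nodes(rep, selection_rule("degree", "mean")),
                   "a")
  expect_identical(select_key_nodes(rep, "degree>2xmedian"), character(0))
  expect_identical(select_key_nodes(rep, "degree>fixed:5"),
                   c("a", "b", "c"))
  # all-equal degrees: nothing strictly exceeds the mean
  flat <- data.frame(id = letters[1:4], degree = rep(3, 4))
  expect_length(select_key_nodes(flat, "degree>mean"), 0)
  expect_error(select_key_nodes(rep[0, ], "degree>mean"), "empty")
})

test_that("selection is monotone non-increasing in the multiplier", {
  withr::with_seed(5, {
    rep <- data.frame(id = sprintf("g%02d", 1:30),
                      degree = rpois(30, 8))
    sizes <- vapply(c(0.5, 1, 1.5, 2, 3), function(m)
      length(select_key_nodes(rep, selection_rule("degree", "mean", m))),
      numeric(1))
    expect_true(all(diff(sizes) <= 0))
  })
})

test_that("the rule mini-grammar parses thresholds and references", {
  r <- parse_selection_rule("degree>2xmean")
  expect_equal(r$measure, "degree")
  expect_equal(r$multiplier, 2)
  expect_equal(r$reference, "mean")
  r <- parse_selection_rule("betweenness>1.5xmedian")
  expect_equal(r$multiplier, 1.5)
  r <- parse_selection_rule("degree>2xfixed:13.833")
  expect_equal(r$reference, "fixed")
  expect_equal(r$fixed_value, 13.833)
  r <- parse_selection_rule("degree>8.09")
  expect_equal(r$reference, "fixed")
  expect_equal(r$multiplier * r$fixed_value, 8.09)
  expect_error(parse_selection_rule("pagerank>2xmean"), "parse")
  expect_error(selection_rule("degree", "fixed"), "fixed_value")
})

test_that("role filters restrict candidates, optionally the reference too", {
  rep <- data.frame(id = c("i1", "i2", "t1", "t2"),
                    role = c("ingredient", "ingredient", "target", "target"),
                    degree = c(10, 8, 4, 2))
  # reference over all nodes (mean 6) by default
  expect_identical(select_key_nodes(rep, "degree>mean", roles = "target"),
                   character(0))
  # reference within the filtered roles (mean 3)
  expect_identical(select_key_nodes(rep, "degree>mean", roles = "target",
                                    reference_within_roles = TRUE),
                   "t1")
})
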