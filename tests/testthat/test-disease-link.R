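chain <- pharm_network(data.frame(id = c("A", "B", "C"), role = "target"),
                       data.frame(from = c("A", "B"), to = c("B", "C"),
                                  kind = "ppi"))

test_that("hop classification on a 3-node chain matches the BFS oracle", {
  cls <- classify_disease_targets("A", chain, c("B", "C", "D"))
  expect_identical(cls$category, c("indirect", "indirect", "unlinked"))
  expect_identical(cls$hop, c(1L, 2L, NA_integer_))
  expect_identical(cls$witness, c("A|B", "A|B|C", NA_character_))
})

test_that("overlap with the formula target set is direct regardless of the PPI", {
  cls <- classify_disease_targets(c("A", "Z"), chain, c("Z", "B"))
  expect_identical(cls$category[cls$gene == "Z"], "direct")
  expect_identical(cls$hop[cls$gene == "Z"], 0L)
  expect_error(classify_disease_targets(character(0), chain, "B"), "empty")
})

test_that("hop limit semantics: max_hop 0 keeps only direct hits", {
  cls0 <- classify_disease_targets("A", chain, c("A", "B", "C"), max_hop = 0)
  expect_identical(cls0$category, c("direct", "unlinked", "unlinked"))
  cls1 <- classify_disease_targets("A", chain, c("A", "B", "C"), max_hop = 1)
  expect_identical(cls1$category, c("direct", "indirect", "unlinked"))
})

test_that("among tied shortest paths the lexicographically smallest witness wins", {
  net <- pharm_network(
    data.frame(id = c("A", "B", "C", "G"), role = "target"),
    data.frame(from = c("A", "A", "B", "C"), to = c("B", "C", "G", "G"),
               kind = "ppi"))
  cls <- classify_disease_targets("A", net, "G")
  expect_identical(cls$witness, "A|B|G")
  # and with two formula targets the smaller starting target wins
  cls <- classify_disease_targets(c("C", "B"), net, "G")
  expect_identical(cls$witness, "B|G")
})

test_that("hops match an all-pairs BFS oracle on random graphs", {
  withr::with_seed(31, {
    for (rep in 1:3) {
      adj <- rand_adj(40, 0.06)
      net <- net_from_adj(adj)
      ids <- rownames(adj)
      ft <- sample(ids, 5)
      disease <- sample(ids, 12)
      cls <- classify_disease_targets(ft, net, disease, max_hop = 100)
      D <- oracle_all_dists(adj)
      for (i in seq_len(nrow(cls))) {
        g <- cls$gene[i]
        expected <- if (g %in% ft) 0 else min(D[match(ft, ids),
                                                match(g, ids)])
        if (is.finite(expected)) {
          expect_equal(cls$hop[i], as.integer(expected))
          # witness is a real path of length hop
          w <- strsplit(cls$witness[i], "|", fixed = TRUE)[[1]]
          expect_length(w, cls$hop[i] + 1)
        } else {
          expect_identical(cls$category[i], "unlinked")
        }
      }
    }
  })
})

test_that("adding PPI edges never increases any gene's hop", {
  withr::with_seed(33, {
    adj <- rand_adj(25, 0.08)
    ids <- rownames(adj)
    ft <- sample(ids, 4)
    disease <- sample(setdiff(ids, ft), 10)
    cls1 <- classify_disease_targets(ft, net_from_adj(adj), disease,
                                     max_hop = 100)
    adj2 <- adj
    extra <- t(utils::combn(25, 2))[sample(300, 20), ]
    for (r in seq_len(nrow(extra))) {
      adj2[extra[r, 1], extra[r, 2]] <- TRUE
      adj2[extra[r, 2], extra[r, 1]] <- TRUE
    }
    cls2 <- classify_disease_targets(ft, net_from_adj(adj2), disease,
                                     max_hop = 100)
    h1 <- ifelse(is.na(cls1$hop), Inf, cls1$hop)
    h2 <- ifelse(is.na(cls2$hop), Inf, cls2$hop)
    expect_true(all(h2 <= h1))
  })
})

test_that("classification summaries count distinct genes by category", {
  cls <- rbind(load_fixture("table5_direct"), load_fixture("table6_indirect"))
  s <- summarize_classification(cls)
  expect_equal(s$n_direct, 14)
  expect_equal(s$n_indirect, 27)
  expect_equal(s$n_total_linked, 41)
  expect_true(all(c("ESR1", "CHEK1", "MAPK14", "BCL2") %in%
                    cls$gene[cls$category == "direct"]))
  expect_true(all(c("CASP8", "HLA-B", "MTOR", "ERBB2") %in%
                    cls$gene[cls$category == "indirect"]))
  empty <- summarize_classification(cls[0, ])
  expect_equal(unlist(empty), c(n_direct = 0, n_indirect = 0,
                                n_total_linked = 0))
})

test_that("the combined network unions tripartite, witnesses and disease genes", {
  tri <- build_tripartite(
    data.frame(mol_id = "M1", name = "x", ob = 50, dl = 0.5, herbs = "H1"),
    data.frame(mol_id = "M1", target_id = "A"))
  ppi <- pharm_network(data.frame(id = c("A", "B"), role = "target"),
                       data.frame(from = "A", to = "B", kind = "ppi",
                                  weight = 0.93))
  cls <- classify_disease_targets("A", ppi, c("B", "Z"))
  comb <- build_combined_network(tri, cls, ppi)
  expect_setequal(unique(comb$nodes$id), c("H1", "M1", "A", "B"))
  expect_equal(nrow(comb$edges), 3)
  # witness edge carries the PPI confidence
  expect_equal(comb$edges$weight[comb$edges$kind == "ppi"], 0.93)
  # unlinked gene Z never appears
  expect_false("Z" %in% comb$nodes$id)
})

test_that("every indirect gene sits within 2 hops of a target in the combined network", {
  sc <- simulate_ppi_scenario(seed = 17)
  ppi <- build_ppi(sc$interactions, min_confidence = 0.9)$network
  cls <- classify_disease_targets(sc$formula_targets, ppi, sc$disease_genes)
  ing <- simulate_ingredients(10, seed = 17)
  map <- data.frame(mol_id = sample(ing$mol_id, length(sc$formula_targets),
                                    replace = TRUE),
                    target_id = sc$formula_targets)
  comb <- build_combined_network(build_tripartite(ing, map), cls, ppi)
  g <- as_igraph(comb)
  targets <- comb$nodes$id[comb$nodes$role == "target"]
  D <- igraph::distances(g, v = unique(targets), weights = NA)
  indirect <- cls$gene[cls$category == "indirect"]
  expect_true(all(apply(D[, indirect, drop = FALSE], 2, min) <= 2))
  unlinked <- cls$gene[cls$category == "unlinked"]
  expect_false(any(unlinked %in% comb$nodes$id))
})
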