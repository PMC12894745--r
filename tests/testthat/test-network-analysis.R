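test_that("betweenness follows the closed forms on canonical graphs", {
  path <- data.frame(source = c("a", "b"), target = c("b", "c"))
  b <- betweenness_table(path)
  expect_equal(b$betweenness[b$name == "b"], 1)
  expect_equal(sum(b$betweenness[b$name != "b"]), 0)

  star <- data.frame(source = "hub", target = paste0("leaf", 1:6))
  bs <- betweenness_table(star)
  expect_equal(bs$betweenness[bs$name == "hub"], 6 * 5 / 2)

  k5 <- clique_edges(5, "n")
  expect_true(all(betweenness_table(k5)$betweenness == 0))
  expect_error(betweenness_table(path[0, ]), "empty")
})

test_that("nominal assortativity hits the perfect mixing limits", {
  two_cliques <- rbind(clique_edges(4, "a"), clique_edges(4, "b"))
  labels <- setNames(rep(c("A", "B"), each = 4),
                     c(paste0("a", 1:4), paste0("b", 1:4)))
  expect_equal(assortativity_nominal(two_cliques, labels), 1)

  bip <- expand.grid(source = paste0("l", 1:3), target = paste0("r", 1:3),
                     stringsAsFactors = FALSE)
  lab_bip <- setNames(rep(c("L", "R"), each = 3),
                      c(paste0("l", 1:3), paste0("r", 1:3)))
  expect_equal(assortativity_nominal(bip, lab_bip), -1)

  # single class: undefined
  expect_message(
    r <- assortativity_nominal(two_cliques,
                               setNames(rep("A", 8), names(labels))),
    "single label")
  expect_true(is.na(r))
})

test_that("assortativity matches igraph on random graphs and is label-name invariant", {
  set.seed(8)
  for (i in 1:30) {
    net <- random_edge_table(sample(6:30, 1), 0.25)
    nodes <- unique(c(net$source, net$target))
    labels <- setNames(sample(letters[1:3], length(nodes), TRUE), nodes)
    if (length(unique(labels)) < 2) labels[1:2] <- c("a", "b")
    g <- igraph::graph_from_data_frame(net, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    oracle <- igraph::assortativity_nominal(
      g, as.integer(factor(labels[igraph::V(g)$name])))
    expect_equal(assortativity_nominal(net, labels), oracle,
                 tolerance = 1e-12)
    # renaming categories does not change r
    renamed <- setNames(c(a = "zebra", b = "yak", c = "x")[labels], nodes)
    expect_equal(assortativity_nominal(net, renamed),
                 assortativity_nominal(net, labels), tolerance = 1e-12)
  }
})

test_that("the label-shuffle z-test separates planted structure from noise", {
  set.seed(9)
  # planted two-block graph: strong within-block connectivity
  blocks <- igraph::sample_sbm(30, matrix(c(0.5, 0.03, 0.03, 0.5), 2),
                               c(15, 15))
  igraph::V(blocks)$name <- paste0("v", 1:30)
  el <- igraph::as_edgelist(blocks)
  net <- data.frame(source = el[, 1], target = el[, 2])
  labels <- setNames(rep(c("x", "y"), each = 15), paste0("v", 1:30))
  zt <- assortativity_ztest(net, labels, n_shuffles = 100, seed = 1)
  expect_gt(zt$z, 3)
  expect_equal(zt$z, (zt$r - zt$null_mean) / zt$null_sd)
})

test_that("edge clustering coefficients match their hand values", {
  # triangle plus a pendant: the pure-triangle edge has both endpoint
  # degrees 2 so ECC = (1 + 1) / 1 = 2
  net <- data.frame(source = c("a", "b", "c", "c"),
                    target = c("b", "c", "a", "d"))
  ecc <- edge_clustering_coefficient(net)
  key <- paste(pmin(ecc$from, ecc$to), pmax(ecc$from, ecc$to))
  expect_equal(ecc$ecc[key == "a b"], 2)
  # pendant edge: degree-1 endpoint forces 0
  expect_equal(ecc$ecc[key == "c d"], 0)
})

test_that("bridged cliques are split into their modules", {
  net <- rbind(clique_edges(6, "a"), clique_edges(6, "b"),
               data.frame(source = "a1", target = "b1"))
  part <- ecc_communities(net, min_size = 5)
  expect_length(part$modules, 2)
  expect_equal(sort(vapply(part$modules, length, integer(1))), c(6L, 6L))
  expect_setequal(part$modules[[1]], paste0("a", 1:6))
  expect_setequal(part$modules[[2]], paste0("b", 1:6))
  expect_length(part$unassigned, 0)

  # sub-threshold graphs report no modules
  small <- data.frame(source = c("a", "b", "c"), target = c("b", "c", "d"))
  part2 <- ecc_communities(small, min_size = 5)
  expect_length(part2$modules, 0)
  expect_setequal(part2$unassigned, c("a", "b", "c", "d"))

  # deterministic
  expect_identical(ecc_communities(net, 5), ecc_communities(net, 5))
})

test_that("module feature tables count and flag majorities consistently", {
  ann <- data.frame(name = c(paste0("a", 1:6), paste0("b", 1:6)),
                    condition_tag = rep(c("autologous", "monoculture"),
                                        each = 6),
                    patient_tag = c(rep("p2", 6), rep("shared", 6)),
                    time_tag = "d1-d4")
  net <- rbind(clique_edges(6, "a"), clique_edges(6, "b"),
               data.frame(source = "a1", target = "b1"))
  part <- ecc_communities(net, 5)
  tab <- module_feature_table(part, ann)
  for (m in unique(tab$module)) {
    sums <- tapply(tab$count[tab$module == m], tab$feature[tab$module == m],
                   sum)
    expect_true(all(sums == length(part$modules[[m]])))
  }
  m_a <- unique(tab$module[tab$class == "p2" & tab$count == 6])
  expect_true(all(tab$majority[tab$module == m_a & tab$class == "p2"]))
  empty <- module_feature_table(list(modules = list()), ann)
  expect_equal(nrow(empty), 0)
})

test_that("node annotations collapse multi-membership to shared categories", {
  da <- data.frame(tf = c("A", "B"),
                   conditions = c("autologous", "autologous,monoculture"),
                   patients = c("p1,p3", "p2"),
                   intervals = c("d1-d4", "d1-d4,d8-d11"),
                   n_hits = c(2, 3))
  ann <- annotate_nodes(da)
  expect_identical(ann$condition_tag, c("autologous", "both"))
  expect_identical(ann$patient_tag, c("shared", "p2"))
  expect_identical(ann$time_tag, c("d1-d4", "multiple"))
})
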