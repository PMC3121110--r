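test_that("star and path graphs show the expected centrality extremes", {
  star <- star_graph("hub", paste0("l", 1:4))
  cent <- compute_centralities(star)
  hub <- cent[cent$node == "hub", ]
  leaves <- cent[cent$node != "hub", ]
  expect_equal(hub$betweenness, 1)
  expect_true(all(hub$closeness > leaves$closeness))
  expect_true(all(hub$pagerank > leaves$pagerank))

  path <- path_graph(c("a", "b", "c"))
  cent <- compute_centralities(path)
  expect_equal(cent$betweenness[cent$node == "b"], 1)
  expect_equal(cent$betweenness[cent$node %in% c("a", "c")], c(0, 0))
})

test_that("centralities match brute-force oracles on assorted graphs", {
  set.seed(13)
  graphs <- list(
    path_graph(paste0("p", 1:7)),
    star_graph("hub", paste0("l", 1:6)),
    cycle_graph(paste0("c", 1:8)),
    random_test_graph(15),
    random_test_graph(20, extra = 30)
  )
  for (net in graphs) {
    cent <- compute_centralities(net)
    expect_equal(
      stats::setNames(cent$betweenness, cent$node),
      oracle_betweenness(net)[cent$node],
      tolerance = 1e-8
    )
    expect_equal(
      stats::setNames(cent$closeness, cent$node),
      oracle_harmonic_closeness(net)[cent$node],
      tolerance = 1e-8
    )
    expect_equal(
      stats::setNames(cent$pagerank, cent$node),
      oracle_pagerank(net)[cent$node],
      tolerance = 1e-8
    )
    expect_equal(sum(cent$pagerank), 1, tolerance = 1e-10)
  }
})

test_that("pagerank sums to one and betweenness stays normalized on random graphs", {
  set.seed(31)
  for (rep in 1:5) {
    net <- random_test_graph(sample(10:20, 1))
    cent <- compute_centralities(net)
    expect_true(all(cent$betweenness >= 0 & cent$betweenness <= 1))
    expect_true(all(cent$closeness >= 0 & cent$closeness <= 1))
    expect_equal(sum(cent$pagerank), 1, tolerance = 1e-10)
  }
})

test_that("perfectly correlated centrality columns collapse onto PC1", {
  x <- tibble::tibble(
    node = paste0("n", 1:6),
    betweenness = 1:6 / 10,
    closeness = (1:6) * 2 + 5,
    pagerank = (1:6) / 21
  )
  ni <- node_importance(x)
  expect_equal(ni$explained_variance, 1.0, tolerance = 1e-9)
  expect_identical(order(ni$importance$ip), 1:6)
  expect_equal(range(ni$importance$ip), c(0, 1))
})

test_that("constant centralities yield zero importance with a warning", {
  x <- tibble::tibble(
    node = paste0("n", 1:4),
    betweenness = rep(0.5, 4), closeness = rep(0.2, 4), pagerank = rep(0.25, 4)
  )
  expect_warning(ni <- node_importance(x), "constant")
  expect_true(all(ni$importance$ip == 0))
  expect_true(is.na(ni$explained_variance))
})

test_that("importance is equivariant under node relabeling", {
  set.seed(23)
  net <- random_test_graph(25)
  ni <- node_importance(net)
  cent <- compute_centralities(net)
  perm <- sample(nrow(cent))
  ni_perm <- node_importance(cent[perm, ])
  merged <- merge(ni$importance, ni_perm$importance,
    by = "node", suffixes = c("", "_perm")
  )
  expect_equal(merged$ip, merged$ip_perm, tolerance = 1e-12)
})

test_that("importance tracks degree on scale-free graphs (sign convention)", {
  set.seed(77)
  net <- simulate_network(250, "scale_free", edges_per_node = 2)
  ni <- node_importance(net)
  expect_gt(ni$explained_variance, 0.6)
  deg <- igraph::degree(net)[ni$importance$node]
  expect_gt(cor(ni$importance$ip, deg, method = "spearman"), 0)
  top <- deg >= stats::quantile(deg, 0.9)
  bottom <- deg <= stats::quantile(deg, 0.1)
  expect_gt(mean(ni$importance$ip[top]), mean(ni$importance$ip[bottom]))
})

test_that("degree can be integrated as a fourth measure", {
  set.seed(3)
  net <- random_test_graph(20)
  ni <- node_importance(net, measures = c("betweenness", "closeness", "pagerank", "degree"))
  expect_length(ni$loadings, 4)
  expect_true(all(c("degree", "ip") %in% names(tidy(ni))))
})

test_that("tidy and glance expose the per-node table and the summary", {
  set.seed(4)
  net <- random_test_graph(12)
  ni <- node_importance(net)
  td <- tidy(ni)
  expect_true(all(c("node", "betweenness", "closeness", "pagerank", "ip") %in% names(td)))
  expect_equal(nrow(td), 12)
  g <- glance(ni)
  expect_equal(g$n_nodes, 12)
  expect_true(g$explained_variance > 0 && g$explained_variance <= 1)
})
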