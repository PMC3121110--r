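test_that("edge-list loading deduplicates edges and drops self-loops", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\tc", "b\tc"), tf)
  net <- read_network(tf, quiet = TRUE)
  expect_setequal(igraph::V(net)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(net), 2)

  writeLines(c("a\ta", "a\tb"), tf)
  expect_warning(net <- read_network(tf, quiet = TRUE), "self-loop")
  expect_equal(igraph::ecount(net), 1)
})

test_that("SIF is accepted and malformed lines are reported by number", {
  tf <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("# comment", "a pp b", "b pp c"), tf)
  net <- read_network(tf, quiet = TRUE)
  expect_equal(igraph::ecount(net), 2)

  writeLines(c("a\tb", "c"), tf)
  expect_error(read_network(tf, quiet = TRUE), "line 2")
  writeLines(character(), tf)
  expect_error(read_network(tf, quiet = TRUE), "no edges")
})

test_that("loaded node set equals the union of file endpoints", {
  set.seed(41)
  labels <- sprintf("v%d", 1:12)
  from <- sample(labels, 10, replace = TRUE)
  to <- sample(labels, 10, replace = TRUE)
  keep <- from != to
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(from[keep], to[keep], sep = "\t"), tf)
  net <- read_network(tf, quiet = TRUE)
  expect_setequal(igraph::V(net)$name, union(from[keep], to[keep]))
})

test_that("write/read round-trip preserves the node and edge sets", {
  set.seed(5)
  net <- random_test_graph(15)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, tf, header = "round trip")
  back <- read_network(tf, quiet = TRUE)
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_identical(key(back), key(net))
})

test_that("min_distance handles membership, paths and disconnection", {
  net <- path_graph(c("a", "b", "c", "d"))
  expect_equal(min_distance(net, "a", "d"), 3)
  expect_equal(min_distance(net, "a", c("a", "d")), 0)
  two_comp <- background_network(c("a", "x"), c("b", "y"))
  expect_equal(min_distance(two_comp, "a", "y"), Inf)
  expect_error(min_distance(net, "zz", "a"), "zz")
})

test_that("min_distance agrees with brute-force BFS on random networks", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    net <- random_test_graph(n, extra = sample(0:n, 1))
    d <- oracle_distances(net)
    nodes <- igraph::V(net)$name
    src <- sample(nodes, 1)
    targets <- sample(nodes, sample(1:4, 1))
    expect_equal(min_distance(net, src, targets), min(d[src, targets]))
  }
})

test_that("node-group collapsing follows keep and merge conventions", {
  # No cross-pair of K1={a,b}, K2={c,d} members is adjacent: no edge.
  net <- background_network(c("a", "c"), c("b", "d"))
  kept <- merge_node_groups(net, list(K1 = c("a", "b"), K2 = c("c", "d")), "keep")
  expect_setequal(igraph::V(kept)$name, c("K1", "K2"))
  expect_equal(igraph::ecount(kept), 0)

  # Overlapping groups K1={a,b}, K2={b,c}: the a-b cross pair (b sits in
  # K2 too) is adjacent, so keep mode links the two group nodes.
  groups <- list(K1 = c("a", "b"), K2 = c("b", "c"))
  net2 <- background_network(c("a", "b"), c("b", "c"))
  kept2 <- merge_node_groups(net2, groups, mode = "keep")
  expect_setequal(igraph::V(kept2)$name, c("K1", "K2"))
  expect_equal(igraph::ecount(kept2), 1)

  merged <- merge_node_groups(net2, groups, mode = "merge")
  expect_equal(igraph::vcount(merged), 1)
  expect_equal(igraph::ecount(merged), 0)
  expect_setequal(igraph::V(merged)$members[[1]], c("a", "b", "c"))
})

test_that("singleton groups reproduce the network and errors are raised", {
  net <- background_network(c("a", "b"), c("b", "c"))
  groups <- list(a = "a", b = "b", c = "c")
  for (mode in c("keep", "merge")) {
    out <- merge_node_groups(net, groups, mode = mode)
    expect_setequal(igraph::V(out)$name, c("a", "b", "c"))
    expect_equal(igraph::ecount(out), 2)
  }
  expect_error(merge_node_groups(net, list(G = character())), "Empty group")
  expect_warning(
    merge_node_groups(net, list(G1 = c("a", "zz"), G2 = "b")),
    "unknown node"
  )
})

test_that("merge mode never yields more nodes than keep mode", {
  set.seed(7)
  for (rep in 1:10) {
    net <- random_test_graph(12)
    nodes <- igraph::V(net)$name
    groups <- lapply(1:4, function(.) sample(nodes, sample(2:4, 1)))
    names(groups) <- paste0("G", 1:4)
    n_keep <- igraph::vcount(merge_node_groups(net, groups, "keep"))
    n_merge <- igraph::vcount(merge_node_groups(net, groups, "merge"))
    expect_lte(n_merge, n_keep)
  }
})

test_that("pair subnetwork is the union of nearest shortest paths", {
  net <- path_graph(c("a", "b", "c", "d"))
  sub <- extract_pair_subnetwork(net, "a", "d")
  expect_setequal(igraph::V(sub)$name, c("a", "b", "c", "d"))
  expect_equal(igraph::ecount(sub), 3)

  sub1 <- extract_pair_subnetwork(net, "a", "a")
  expect_identical(igraph::V(sub1)$name, "a")
  expect_equal(igraph::ecount(sub1), 0)

  star <- star_graph("hub", c("l1", "l2", "l3"))
  sub2 <- extract_pair_subnetwork(star, "l1", "l2")
  expect_setequal(igraph::V(sub2)$name, c("l1", "hub", "l2"))

  expect_error(extract_pair_subnetwork(net, "zz", "ww"), "Neither")
})
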