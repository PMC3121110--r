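ts_row <- function(ts, ids = c("A1", "A2")) {
  tibble::tibble(agent_1 = ids[1], agent_2 = ids[2], ts = ts)
}
as_row <- function(as_value, ids = c("A1", "A2")) {
  tibble::tibble(agent_1 = ids[1], agent_2 = ids[2], as_value = as_value)
}

test_that("synergy score is the TS x AS product with the validity band", {
  res <- synergy_score(ts_row(0.5), as_row(0.4))
  expect_equal(res$s, 0.2)
  expect_true(res$valid)

  res <- synergy_score(ts_row(1.0), as_row(1.0))
  expect_identical(res$s, 1)
  expect_false(res$valid)

  res <- synergy_score(ts_row(0.81), as_row(0.26))
  expect_equal(res$s, 0.2106, tolerance = 1e-12)
  expect_true(res$valid)

  # reversed pair ids still match; disjoint pairs do not
  expect_silent(synergy_score(ts_row(0.5), as_row(0.4, ids = c("A2", "A1"))))
  expect_error(synergy_score(ts_row(0.5), as_row(0.4, ids = c("A1", "A3"))), "mismatch")
})

test_that("identical agents score exactly 1 and are flagged invalid", {
  set.seed(8)
  net <- random_test_graph(20)
  ni <- node_importance(net)
  sim <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("p", "q"), c("p", "q")))
  agents <- tibble::tibble(
    agent_id = c("A1", "A2"),
    genes = list(igraph::V(net)$name[1:5], igraph::V(net)$name[1:5]),
    phenotypes = list("p", "p")
  )
  tab <- synergy_table(agents, net, ni, sim)
  expect_identical(tab$s, 1)
  expect_false(tab$valid)
})

test_that("partner ranking sorts by S with deterministic tie-breaking", {
  set.seed(15)
  net <- random_test_graph(40)
  nodes <- igraph::V(net)$name
  agents <- tibble::tibble(
    agent_id = sprintf("A%02d", 1:8),
    genes = lapply(1:8, function(.) sample(nodes, 4)),
    phenotypes = rep(list(character()), 8)
  )
  ranking <- rank_partners(agents, "A01", net)
  expect_s3_class(ranking, "synergy_ranking")
  expect_equal(nrow(ranking), 7)
  valid <- ranking[ranking$valid, ]
  expect_identical(valid$rank, seq_len(nrow(valid)))
  expect_true(all(diff(valid$s) <= 1e-12))
  expect_error(rank_partners(agents, "missing", net), "not among")
})

test_that("equal-S ties rank the higher-TS pair first", {
  # Two partners identical in every score except TS (AS compensating).
  path <- path_graph(paste0("v", 1:6))
  ip <- uniform_ip(path)
  sim_ids <- c("p1", "p2", "q")
  sim <- matrix(0.5, 3, 3, dimnames = list(sim_ids, sim_ids))
  # S(seed, B) = TS(B) * P(p1, q); pick similarities so the products tie.
  ts_b <- exp(-1) # v2 at distance 1 from seed at v1
  ts_c <- exp(-2) # v3 at distance 2
  sim["p1", "q"] <- sim["q", "p1"] <- 0.2
  sim["p2", "q"] <- sim["q", "p2"] <- 0.2 * ts_b / ts_c
  diag(sim) <- 1
  agents <- tibble::tibble(
    agent_id = c("seed", "B", "C"),
    genes = list("v1", "v2", "v3"),
    phenotypes = list("q", "p1", "p2")
  )
  ranking <- rank_partners(agents, "seed", path, ip, sim)
  expect_equal(ranking$s[1], ranking$s[2], tolerance = 1e-12)
  expect_identical(ranking$partner[1], "B") # higher TS wins the tie
})

test_that("meet/min matches its closed forms and dominates Jaccard", {
  expect_equal(meet_min(c("a", "b"), c("a", "b", "c")), 1.0)
  expect_equal(meet_min(c("a", "b"), c("x", "y")), 0.0)
  expect_equal(meet_min(c("a", "b", "c"), c("b", "c", "d", "e")), 2 / 3)
  expect_error(meet_min(character(), "a"), "non-empty")

  set.seed(29)
  pool <- letters
  for (rep in 1:25) {
    g1 <- sample(pool, sample(1:10, 1))
    g2 <- sample(pool, sample(1:10, 1))
    jaccard <- length(intersect(g1, g2)) / length(union(g1, g2))
    expect_gte(meet_min(g1, g2), jaccard)
  }
})

test_that("GO UI score is intersection over union of pooled term sets", {
  ann <- tibble::tibble(
    gene = c("g1", "g1", "g2", "g3", "g3", "g4"),
    term = c("t1", "t2", "t2", "t3", "t4", "t2")
  )
  expect_equal(go_ui_score(c("g1"), c("g1"), ann), 1.0)
  expect_equal(go_ui_score("g1", "g3", ann), 0.0)
  # terms {t1,t2} vs {t2,t3,t4} -> 1/4
  expect_equal(go_ui_score("g1", c("g3", "g4"), ann), 1 / 4)
  expect_warning(ui <- go_ui_score("gX", "gY", ann), "GO annotations")
  expect_equal(ui, 0)
  # named-list annotation form agrees
  lst <- split(ann$term, ann$gene)
  expect_equal(go_ui_score("g1", c("g3", "g4"), lst), 1 / 4)
})

test_that("Spearman correlation handles perfect, reversed and tied orderings", {
  expect_equal(srcc(1:5, 2 * (1:5) + 3), 1.0)
  expect_equal(srcc(1:5, rev(1:5)), -1.0)
  expect_equal(srcc(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(srcc(1:4, 1:5), "equal length")
  expect_error(srcc(1:2, 1:2), "at least 3")
})
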