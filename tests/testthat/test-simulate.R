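test_that("scenario generation is byte-identical under one seed", {
  args <- list(
    n_nodes = 200, edges_per_node = 2, n_agents = 10,
    genes_range = c(5, 12), n_phenotypes = 12, n_blocks = 3, seed = 42
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_scenario(do.call(simulate_scenario, args), d1)
  p2 <- write_scenario(do.call(simulate_scenario, args), d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
})

test_that("per-agent gene counts respect the requested range", {
  sc <- simulate_scenario(
    n_nodes = 400, n_agents = 20, genes_range = c(10, 30),
    seed = 3
  )
  counts <- lengths(sc$agents$genes)
  expect_true(all(counts >= 10 & counts <= 30))
  expect_true(all(unlist(sc$agents$genes) %in% igraph::V(sc$network)$name))
})

test_that("hub-adjacent placement lands on high-degree nodes", {
  sc <- simulate_scenario(
    n_nodes = 400, n_agents = 4, genes_range = c(5, 10),
    placement = c("hub_adjacent", "hub_adjacent", "peripheral", "peripheral"),
    seed = 8
  )
  deg <- igraph::degree(sc$network)
  pct <- rank(deg) / length(deg)
  hub_pct <- mean(pct[unlist(sc$agents$genes[1:2])])
  peri_pct <- mean(pct[unlist(sc$agents$genes[3:4])])
  expect_gt(hub_pct, 0.8)
  expect_lt(peri_pct, hub_pct)
})

test_that("unsatisfiable hub placement raises an error", {
  expect_error(
    simulate_scenario(
      n_nodes = 50, n_agents = 2, genes_range = c(40, 40),
      placement = "hub_adjacent", seed = 1
    ),
    "Unsatisfiable"
  )
})

test_that("pairing plants shared phenotype blocks and a manifest truth", {
  sc <- simulate_scenario(
    n_nodes = 300, n_agents = 6, genes_range = c(5, 8),
    placement = c("hub_adjacent", "hub_adjacent", "peripheral", "peripheral", "random", "random"),
    pairing = c(1, 1, NA, NA, NA, NA), seed = 21
  )
  man <- sc$manifest
  expect_equal(nrow(man), choose(6, 2))
  planted <- man[man$planted_synergistic, ]
  expect_identical(planted$agent_1, "agent01")
  expect_identical(planted$agent_2, "agent02")
  expect_true(man$planted_null[man$agent_1 == "agent03" & man$agent_2 == "agent04"])
  # paired agents share a phenotype block: their mean cross similarity is high
  as_pair <- agent_score(
    sc$agents$phenotypes[[1]], sc$agents$phenotypes[[2]],
    sc$phenotype_similarity
  )
  expect_gt(as_pair$as_value, 0.5)
})

test_that("generated files load back through the standard readers", {
  sc <- simulate_scenario(
    n_nodes = 150, n_agents = 5, genes_range = c(4, 8),
    n_phenotypes = 8, n_blocks = 2, seed = 17
  )
  dir <- withr::local_tempdir()
  paths <- write_scenario(sc, dir)
  expect_no_warning({
    net <- read_network(paths[["network"]], quiet = TRUE)
    agents <- read_agents(paths[["agents"]])
    agents <- add_phenotypes(agents, read_phenotype_membership(paths[["membership"]]))
    sim <- read_phenotype_similarity(paths[["similarity"]])
    ann <- read_go_annotations(paths[["go"]])
  })
  expect_equal(igraph::vcount(net), 150)
  expect_identical(agents$agent_id, sc$agents$agent_id)
  expect_equal(sim, sc$phenotype_similarity, tolerance = 1e-12)
  expect_setequal(
    purrr::map2_lgl(agents$genes, sc$agents$genes, setequal), TRUE
  )
  expect_setequal(
    purrr::map2_lgl(agents$phenotypes, sc$agents$phenotypes, setequal), TRUE
  )
  expect_equal(nrow(ann), nrow(sc$go_annotations))
})

test_that("noiseless dose-response planting is recovered exactly", {
  tab <- simulate_dose_response(n_doses = 8, planted_miir = 0.15, noise_sd = 0)
  res <- miir(tab)
  expect_equal(res$miir, 0.15, tolerance = 1e-12)
  expect_equal(res$dose_index, attr(tab, "peak_index"))
  single <- simulate_dose_response(n_doses = 1, planted_miir = 0.1)
  expect_equal(nrow(single), 1)
})

test_that("null dose-response planting stays within the noise envelope", {
  set.seed(6)
  noise_sd <- 0.02
  recovered <- vapply(1:100, function(s) {
    miir(simulate_dose_response(
      n_doses = 6, planted_miir = 0, noise_sd = noise_sd, seed = s
    ))$miir
  }, 1)
  # max of 6 mean-zero draws: should essentially never exceed 3 sd
  expect_lt(mean(abs(recovered) > 3 * noise_sd), 0.05)
  expect_true(all(recovered >= -3.9 * noise_sd & recovered <= 3.9 * noise_sd))
})

test_that("single-agent curves are monotone in dose", {
  tab <- simulate_dose_response(n_doses = 10, planted_miir = 0.1)
  expect_true(all(diff(tab$ir1) > 0))
  expect_true(all(diff(tab$ir2) > 0))
  expect_equal(tab$dose2 / tab$dose1, rep(10, 10))
})
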