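#' Simulate a background network
#'
#' Default topology is scale-free (preferential attachment), matching the
#' heavy-tailed degree structure of curated disease networks; Erdős–Rényi
#' and 2-d lattice topologies are available as contrasts.
#'
#' @param n_nodes Number of gene nodes.
#' @param model `"scale_free"`, `"random"`, or `"lattice"`.
#' @param edges_per_node Attachment parameter (scale-free) or mean edges
#'   per node (random); ignored for the lattice.
#' @param seed Optional integer for a reproducible draw.
#' @return An undirected igraph graph with node names `g0001`, `g0002`, ...
#' @export
simulate_network <- function(n_nodes, model = c("scale_free", "random", "lattice"),
                             edges_per_node = 3, seed = NULL) {
  model <- match.arg(model)
  if (n_nodes < 2) {
    abort("`n_nodes` must be at least 2.")
  }
  net <- with_seed(seed, switch(model,
    scale_free = igraph::sample_pa(n_nodes,
      power = 1, m = edges_per_node,
      directed = FALSE
    ),
    random = igraph::sample_gnm(n_nodes, min(
      edges_per_node * n_nodes,
      n_nodes * (n_nodes - 1) / 2
    )),
    lattice = {
      r <- floor(sqrt(n_nodes))
      g <- igraph::make_lattice(c(r, ceiling(n_nodes / r)))
      igraph::delete_vertices(g, seq_len(igraph::vcount(g) - n_nodes) + n_nodes)
    }
  ))
  net <- igraph::simplify(net)
  igraph::V(net)$name <- sprintf("g%0*d", nchar(n_nodes), seq_len(n_nodes))
  igraph::graph_attr(net, "name") <- sprintf("simulated_%s_%d", model, n_nodes)
  net
}

#' Simulate a complete scoring scenario with plantable structure
#'
#' Generates every input the scoring pipeline consumes: a background
#' network, agent gene sets with controllable network placement, a
#' block-structured phenotype-similarity matrix, and gene-to-GO-term
#' annotations. Defaults mirror the study conditions the method was
#' developed under: a 2707-node scale-free disease network and 63 agents
#' whose gene counts range from 10 to 108.
#'
#' Placement policies control where an agent's genes fall:
#' * `"random"` — uniform over all nodes;
#' * `"hub_adjacent"` — drawn from the top-decile-degree nodes, which in a
#'   scale-free graph are both important and mutually close;
#' * `"peripheral"` — drawn from the low-degree half of the nodes nearest a
#'   low-degree anchor, giving a localized peripheral footprint;
#' * `"module_targeted"` — the nodes nearest a random anchor (a local
#'   module regardless of degree).
#'
#' `pairing` plants synergistic structure: agents sharing a pairing id use
#' the same anchor/pool (so their gene sets are network-adjacent) and the
#' same phenotype block (so their agent score is high). The returned
#' manifest records, for every unordered agent pair, whether it was planted
#' as synergistic (same pairing group of hub-adjacent agents) or as a null
#' pair (unrelated peripheral agents).
#'
#' @param n_nodes,model,edges_per_node Passed to [simulate_network()].
#' @param n_agents Number of agents.
#' @param genes_range Integer range the per-agent gene count is drawn from.
#' @param placement Placement policy per agent (recycled).
#' @param pairing Optional vector of pairing ids per agent (`NA` =
#'   unpaired).
#' @param n_phenotypes,n_blocks Size and block count of the similarity
#'   matrix.
#' @param sim_within,sim_between,sim_noise Within-block and between-block
#'   similarity levels and the s.d. of symmetric Gaussian jitter (values
#'   are clipped back to \[0, 1\]).
#' @param phenotypes_per_agent Phenotypes drawn for each agent from its
#'   block.
#' @param n_go_terms,go_terms_per_gene GO annotation pool size and terms
#'   drawn per gene.
#' @param seed Master seed; the whole scenario is reproducible from it.
#' @return A list of class `synergy_scenario`: `network`, `agents`,
#'   `phenotype_similarity`, `go_annotations`, `manifest`, `seed`.
#' @export
simulate_scenario <- function(n_nodes = 2707,
                              model = "scale_free",
                              edges_per_node = 3,
                              n_agents = 63,
                              genes_range = c(10, 108),
                              placement = "random",
                              pairing = NULL,
                              n_phenotypes = 50,
                              n_blocks = 5,
                              sim_within = 0.7,
                              sim_between = 0.1,
                              sim_noise = 0.03,
                              phenotypes_per_agent = 3,
                              n_go_terms = 40,
                              go_terms_per_gene = 3,
                              seed = NULL) {
  if (n_agents < 2) {
    abort("`n_agents` must be at least 2.")
  }
  placement <- rep_len(placement, n_agents)
  bad <- setdiff(placement, c("random", "hub_adjacent", "peripheral", "module_targeted"))
  if (length(bad) > 0) {
    abort(sprintf("Unknown placement policy: %s", paste(bad, collapse = ", ")))
  }
  pairing <- if (is.null(pairing)) rep(NA_integer_, n_agents) else rep_len(pairing, n_agents)

  with_seed(seed, {
    net <- simulate_network(n_nodes, model, edges_per_node)
    nodes <- node_ids(net)
    deg <- igraph::degree(net)
    hub_pool <- nodes[deg >= stats::quantile(deg, 0.9)]
    low_pool <- nodes[deg <= stats::quantile(deg, 0.5)]

    n_genes <- sample(genes_range[1]:genes_range[2], n_agents, replace = TRUE)
    if (any(placement == "hub_adjacent" & n_genes > length(hub_pool))) {
      abort(sprintf(
        "Unsatisfiable placement: hub-adjacent agents need up to %d genes but only %d top-decile-degree nodes exist.",
        max(n_genes[placement == "hub_adjacent"]), length(hub_pool)
      ))
    }

    # Shared anchors per pairing group so "near" placement is guaranteed.
    anchor_for <- new.env(parent = emptyenv())
    pick_anchor <- function(i, pool) {
      key <- if (is.na(pairing[i])) paste0(".agent", i) else paste0(".grp", pairing[i])
      if (is.null(anchor_for[[key]])) {
        anchor_for[[key]] <- sample_from(pool, 1)
      }
      anchor_for[[key]]
    }
    nearest_in <- function(anchor, pool, k) {
      d <- igraph::distances(net, v = anchor, to = pool)[1, ]
      pool <- pool[is.finite(d)]
      d <- d[is.finite(d)]
      if (length(pool) < k) {
        abort(sprintf(
          "Unsatisfiable placement: only %d reachable candidate nodes for %d genes.",
          length(pool), k
        ))
      }
      # nearest k, random order among distance ties
      ord <- order(d + runif(length(d)) * 0.5)
      pool[ord][seq_len(k)]
    }
    genes <- purrr::map(seq_len(n_agents), function(i) {
      k <- n_genes[i]
      switch(placement[i],
        random = sample_from(nodes, k),
        hub_adjacent = sample_from(hub_pool, k),
        peripheral = nearest_in(pick_anchor(i, low_pool), low_pool, k),
        module_targeted = nearest_in(pick_anchor(i, nodes), nodes, k)
      )
    })

    # Block-structured phenotype similarity.
    block_of_ph <- rep_len(seq_len(n_blocks), n_phenotypes)
    ph_ids <- sprintf("ph%02d", seq_len(n_phenotypes))
    sim <- matrix(sim_between, n_phenotypes, n_phenotypes,
      dimnames = list(ph_ids, ph_ids)
    )
    same_block <- outer(block_of_ph, block_of_ph, `==`)
    sim[same_block] <- sim_within
    if (sim_noise > 0) {
      jitter <- matrix(stats::rnorm(n_phenotypes^2, 0, sim_noise), n_phenotypes)
      sim <- sim + (jitter + t(jitter)) / 2
      sim <- pmin(pmax(sim, 0), 1)
    }
    diag(sim) <- 1

    # Agent phenotype sets: one block per pairing group / unpaired agent.
    block_for <- new.env(parent = emptyenv())
    agent_block <- vapply(seq_len(n_agents), function(i) {
      key <- if (is.na(pairing[i])) paste0(".agent", i) else paste0(".grp", pairing[i])
      if (is.null(block_for[[key]])) {
        block_for[[key]] <- sample.int(n_blocks, 1)
      }
      block_for[[key]]
    }, 1L)
    phenotypes <- purrr::map(agent_block, function(b) {
      pool <- ph_ids[block_of_ph == b]
      sample_from(pool, min(phenotypes_per_agent, length(pool)))
    })

    agents <- tibble(
      agent_id = sprintf("agent%02d", seq_len(n_agents)),
      description = sprintf("%s%s", placement,
        ifelse(is.na(pairing), "", sprintf("_grp%d", pairing))
      ),
      genes = genes,
      phenotypes = phenotypes
    )

    go_terms <- sprintf("GO:%07d", seq_len(n_go_terms))
    go_annotations <- tibble(
      gene = rep(nodes, each = go_terms_per_gene),
      term = unlist(purrr::map(
        nodes,
        function(.) sample_from(go_terms, go_terms_per_gene)
      ))
    )

    idx <- which(upper.tri(diag(n_agents)), arr.ind = TRUE)
    manifest <- tibble(
      agent_1 = agents$agent_id[idx[, "row"]],
      agent_2 = agents$agent_id[idx[, "col"]],
      placement_1 = placement[idx[, "row"]],
      placement_2 = placement[idx[, "col"]],
      same_group = !is.na(pairing[idx[, "row"]]) &
        !is.na(pairing[idx[, "col"]]) &
        pairing[idx[, "row"]] == pairing[idx[, "col"]]
    )
    manifest$planted_synergistic <- manifest$same_group &
      manifest$placement_1 == "hub_adjacent" & manifest$placement_2 == "hub_adjacent"
    manifest$planted_null <- !manifest$same_group &
      manifest$placement_1 == "peripheral" & manifest$placement_2 == "peripheral"

    structure(
      list(
        network = net, agents = agents, phenotype_similarity = sim,
        go_annotations = go_annotations, manifest = manifest, seed = seed
      ),
      class = "synergy_scenario"
    )
  })
}

#' @export
print.synergy_scenario <- function(x, ...) {
  cat(sprintf(
    "<synergy_scenario> %d-node network (%d edges), %d agents, %d phenotypes; %d planted synergistic pair(s)\n",
    igraph::vcount(x$network), igraph::ecount(x$network),
    nrow(x$agents), nrow(x$phenotype_similarity),
    sum(x$manifest$planted_synergistic)
  ))
  invisible(x)
}

#' Write a simulated scenario to a directory
#'
#' Emits every artifact in the plain-text exchange format the loaders
#' expect: `network.tsv` (edge list), `agents.gmt`,
#' `phenotype_membership.tsv`, `phenotype_similarity.tsv`,
#' `go_annotations.tsv`, and `manifest.tsv` (the planted truth).
#'
#' @param scenario A `synergy_scenario`.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synergy_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    network = file.path(dir, "network.tsv"),
    agents = file.path(dir, "agents.gmt"),
    membership = file.path(dir, "phenotype_membership.tsv"),
    similarity = file.path(dir, "phenotype_similarity.tsv"),
    go = file.path(dir, "go_annotations.tsv"),
    manifest = file.path(dir, "manifest.tsv")
  )
  write_network(scenario$network, paths[["network"]])
  write_agents(scenario$agents, paths[["agents"]])
  membership <- tidyr::unnest(
    scenario$agents[c("agent_id", "phenotypes")],
    "phenotypes"
  )
  utils::write.table(membership, paths[["membership"]],
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = c("agent_id", "phenotype_id")
  )
  write_phenotype_similarity(scenario$phenotype_similarity, paths[["similarity"]])
  utils::write.table(scenario$go_annotations, paths[["go"]],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(scenario$manifest, paths[["manifest"]],
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(paths)
}

#' Simulate a fixed-ratio dose-response table with a planted MIIR
#'
#' Single-agent curves are monotone Hill curves over a geometric dose grid
#' (the two agents kept at a fixed dose ratio, as in an IC50-ratio design).
#' The combination curve is the Bliss additive expectation plus a localized
#' bump of height `planted_miir` at `peak_index` (half-height shoulders on
#' the neighbouring doses) plus optional Gaussian noise. With zero noise
#' and no clipping, [miir()] recovers `planted_miir` exactly at
#' `peak_index`.
#'
#' @param n_doses Number of dose levels.
#' @param planted_miir Height of the planted synergy bump (may be negative
#'   for sub-additive interaction).
#' @param peak_index Dose index carrying the bump; defaults to the low-dose
#'   third of the series, where the additive expectation leaves headroom.
#' @param noise_sd Gaussian noise s.d. added to the combination curve.
#' @param ic50_ratio Ratio of the two agents' IC50 values (sets the fixed
#'   dose ratio).
#' @param hill Hill coefficient of the single-agent curves.
#' @param max_inhibition Plateau of the single-agent curves; kept below 1
#'   (single agents rarely achieve complete inhibition) so the combination
#'   curve has headroom for the planted bump and noise without clipping.
#' @param seed Optional integer for reproducible noise.
#' @return A dose-response tibble (`dose1`, `dose2`, `ir1`, `ir2`,
#'   `ir_combo`) with the planted values stored in attributes
#'   `planted_miir` and `peak_index`.
#' @export
simulate_dose_response <- function(n_doses = 8, planted_miir = 0.15,
                                   peak_index = NULL, noise_sd = 0,
                                   ic50_ratio = 10, hill = 1.5,
                                   max_inhibition = 0.75, seed = NULL) {
  if (n_doses < 1) {
    abort("`n_doses` must be at least 1.")
  }
  if (abs(planted_miir) > 1) {
    abort("`planted_miir` must lie in [-1, 1].")
  }
  peak_index <- peak_index %||% max(1L, ceiling(n_doses / 3))
  if (peak_index < 1 || peak_index > n_doses) {
    abort("`peak_index` out of range.")
  }
  mult <- if (n_doses == 1) 1 else 2^seq(-3, 3, length.out = n_doses)
  hill_ir <- function(x) max_inhibition * x^hill / (x^hill + 1)
  ir1 <- hill_ir(mult)
  ir2 <- hill_ir(mult)
  ir_add <- bliss_additive(ir1, ir2)
  # Positive synergy is a localized bump; negative (sub-additive) planting
  # depresses the whole curve with its least-negative point at the peak so
  # that max(IR_syn - IR_add) equals planted_miir in either sign.
  if (planted_miir >= 0) {
    bump <- numeric(n_doses)
    bump[peak_index] <- planted_miir
    shoulder <- planted_miir / 2
  } else {
    bump <- rep(planted_miir * 1.5, n_doses)
    bump[peak_index] <- planted_miir
    shoulder <- planted_miir * 1.25
  }
  for (nb in c(peak_index - 1, peak_index + 1)) {
    if (nb >= 1 && nb <= n_doses) bump[nb] <- shoulder
  }
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(n_doses, 0, noise_sd))
  } else {
    numeric(n_doses)
  }
  ir_combo <- ir_add + bump + noise
  if (any(ir_combo > 1 | ir_combo < 0)) {
    warn("Combination inhibition clipped to [0, 1]; planted MIIR may not be exactly recoverable.")
    ir_combo <- pmin(pmax(ir_combo, 0), 1)
  }
  out <- tibble(
    dose1 = mult, dose2 = mult * ic50_ratio,
    ir1 = ir1, ir2 = ir2, ir_combo = ir_combo
  )
  attr(out, "planted_miir") <- planted_miir
  attr(out, "peak_index") <- peak_index
  out
}
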