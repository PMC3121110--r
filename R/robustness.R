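#' Perturb one agent's gene set
#'
#' Adds or removes `round(fraction * |genes|)` genes (half away from zero,
#' at least 1 when `fraction > 0`). Removal picks genes uniformly at random
#' or, with `strategy = "top_ip"`, deterministically removes the genes with
#' the highest node importance — the "key gene" removal that the ranking is
#' expected to be sensitive to. Additions draw uniformly from
#' `gene_pool` minus the current genes (the pool is normally the
#' background-network node set).
#'
#' @param genes Character vector, the agent's current genes.
#' @param fraction Proportion of genes to change, in \[0, 1\].
#' @param direction `"remove"` or `"add"`.
#' @param gene_pool Pool for additions (required when `direction = "add"`).
#' @param strategy `"random"` or `"top_ip"` (removal only).
#' @param importance Named IP vector or [node_importance()] object,
#'   required for `strategy = "top_ip"`; genes missing from it rank lowest.
#' @param seed Optional integer making the draw reproducible without
#'   touching the caller's RNG stream.
#' @return The perturbed character vector of genes.
#' @export
perturb_gene_set <- function(genes, fraction, direction = c("remove", "add"),
                             gene_pool = NULL, strategy = c("random", "top_ip"),
                             importance = NULL, seed = NULL) {
  direction <- match.arg(direction)
  strategy <- match.arg(strategy)
  genes <- unique(as.character(genes))
  k <- n_perturbed(fraction, length(genes))
  if (k == 0) {
    return(genes)
  }
  if (direction == "remove") {
    if (k >= length(genes)) {
      abort(sprintf(
        "Removing %d of %d genes would empty the gene set.", k, length(genes)
      ))
    }
    drop <- if (strategy == "top_ip") {
      if (is.null(importance)) {
        abort("`strategy = \"top_ip\"` requires `importance`.")
      }
      ip <- as_ip(importance)
      w <- ip[genes]
      w[is.na(w)] <- -Inf
      genes[order(-w, genes)][seq_len(k)]
    } else {
      with_seed(seed, sample_from(genes, k))
    }
    setdiff(genes, drop)
  } else {
    if (is.null(gene_pool)) {
      abort("`direction = \"add\"` requires `gene_pool`.")
    }
    pool <- setdiff(unique(as.character(gene_pool)), genes)
    if (length(pool) < k) {
      abort(sprintf(
        "Gene pool has only %d candidates but %d additions requested.",
        length(pool), k
      ))
    }
    c(genes, with_seed(seed, sample_from(pool, k)))
  }
}

#' Perturb every agent's gene set
#'
#' Applies [perturb_gene_set()] to each agent (the protocol's default of
#' perturbing all agents simultaneously per repetition); set
#' `scope = "single"` to perturb one randomly chosen agent and leave the
#' rest untouched.
#'
#' @param agents Agent tibble.
#' @inheritParams perturb_gene_set
#' @param scope `"all"` (default) or `"single"`.
#' @return `agents` with its `genes` list-column perturbed.
#' @export
perturb_agents <- function(agents, fraction, direction = c("remove", "add"),
                           gene_pool = NULL, strategy = c("random", "top_ip"),
                           importance = NULL, seed = NULL, scope = c("all", "single")) {
  direction <- match.arg(direction)
  strategy <- match.arg(strategy)
  scope <- match.arg(scope)
  with_seed(seed, {
    rows <- seq_len(nrow(agents))
    if (scope == "single") {
      rows <- sample.int(nrow(agents), 1)
    }
    for (i in rows) {
      agents$genes[[i]] <- perturb_gene_set(
        agents$genes[[i]], fraction, direction,
        gene_pool = gene_pool, strategy = strategy, importance = importance
      )
    }
    agents
  })
}

#' Perturb the background network's edges
#'
#' Removes `round(fraction * |edges|)` randomly chosen edges, or adds that
#' many edges drawn uniformly from the absent non-self node pairs. The node
#' set is unchanged either way.
#'
#' @param net Background network.
#' @param fraction Proportion of edges to change, in \[0, 1\].
#' @param direction `"remove"` or `"add"`.
#' @param seed Optional integer for a reproducible draw.
#' @return The perturbed igraph network.
#' @export
perturb_edges <- function(net, fraction, direction = c("remove", "add"),
                          seed = NULL) {
  direction <- match.arg(direction)
  assert_network(net)
  m <- igraph::ecount(net)
  k <- n_perturbed(fraction, m)
  if (k == 0) {
    return(net)
  }
  if (direction == "remove") {
    if (k >= m) {
      abort(sprintf("Removing %d of %d edges would leave no edges.", k, m))
    }
    with_seed(seed, igraph::delete_edges(net, sample.int(m, k)))
  } else {
    n <- igraph::vcount(net)
    absent <- n * (n - 1) / 2 - m
    if (absent < k) {
      abort(sprintf(
        "Only %d absent node pairs available but %d additions requested.",
        absent, k
      ))
    }
    with_seed(seed, {
      nodes <- node_ids(net)
      existing <- igraph::as_edgelist(net)
      taken <- pair_key(existing[, 1], existing[, 2])
      new_pairs <- character(0)
      new_edges <- character(0)
      while (length(new_pairs) < k) {
        u <- sample_from(nodes, 1)
        v <- sample_from(nodes, 1)
        if (u == v) next
        key <- pair_key(u, v)
        if (key %in% taken || key %in% new_pairs) next
        new_pairs <- c(new_pairs, key)
        new_edges <- c(new_edges, u, v)
      }
      igraph::add_edges(net, new_edges)
    })
  }
}

#' Permutation-robustness protocol
#'
#' Measures how stable the pairwise synergy ranking is under random
#' perturbation of its inputs. For each requested target and fraction the
#' baseline all-pairs synergy scores are recomputed after perturbation and
#' compared with the unperturbed scores by Spearman rank correlation
#' (SRCC); repetitions are aggregated to mean and standard deviation. Gene
#' perturbations keep the network and node importance fixed and recompute
#' TS; edge perturbations recompute centralities, importance and TS.
#' Defaults follow the protocol of 100 repetitions for gene perturbations
#' and 20 for edge perturbations.
#'
#' @param agents Agent tibble.
#' @param net Background network.
#' @param targets Any of `"agent_genes_remove"`, `"agent_genes_add"`,
#'   `"edges_remove"`, `"edges_add"`.
#' @param fractions Numeric vector of perturbation proportions in \[0, 1\].
#' @param repetitions Named or unnamed overrides of the per-target
#'   repetition counts; `NULL` keeps 100 (genes) / 20 (edges).
#' @param similarity Optional phenotype-similarity matrix (AS is held
#'   fixed under gene perturbation since phenotype sets do not change).
#' @param decay Exponential distance-decay rate for TS.
#' @param strategy Gene-removal strategy, `"random"` or `"top_ip"`.
#' @param scope Perturb `"all"` agents per repetition or a `"single"` one.
#' @param seed Master seed; child seeds are derived per repetition.
#' @return A tibble of class `robustness_report` with one row per
#'   (target, fraction): `mean_srcc`, `sd_srcc`, `n_reps`. The full
#'   per-repetition table is kept in the `"details"` attribute and exposed
#'   by [tidy()].
#' @export
run_robustness <- function(agents, net,
                           targets = c("agent_genes_remove", "edges_remove"),
                           fractions = c(0.1, 0.3, 0.5),
                           repetitions = NULL,
                           similarity = NULL, decay = 1,
                           strategy = c("random", "top_ip"),
                           scope = c("all", "single"),
                           seed = 1L) {
  strategy <- match.arg(strategy)
  scope <- match.arg(scope)
  all_targets <- c(
    "agent_genes_remove", "agent_genes_add",
    "edges_remove", "edges_add"
  )
  targets <- match.arg(targets, all_targets, several.ok = TRUE)
  if (any(fractions < 0 | fractions > 1)) {
    abort("`fractions` must be proportions in [0, 1].")
  }

  importance0 <- node_importance(net)
  baseline <- synergy_table(agents, net, importance0, similarity, decay = decay)
  pool <- node_ids(net)

  default_reps <- function(target) {
    if (grepl("^agent_genes", target)) 100L else 20L
  }
  reps_for <- function(target) {
    if (is.null(repetitions)) {
      return(default_reps(target))
    }
    if (!is.null(names(repetitions)) && target %in% names(repetitions)) {
      return(as.integer(repetitions[[target]]))
    }
    as.integer(repetitions[[1]])
  }

  grid <- tidyr::expand_grid(target = targets, fraction = fractions)
  master_seeds <- child_seeds(seed, nrow(grid))
  details <- purrr::map(seq_len(nrow(grid)), function(g) {
    target <- grid$target[g]
    fraction <- grid$fraction[g]
    n_reps <- reps_for(target)
    rep_seeds <- child_seeds(master_seeds[g], n_reps)
    srccs <- vapply(seq_len(n_reps), function(r) {
      if (fraction == 0) {
        return(1)
      }
      if (grepl("^agent_genes", target)) {
        direction <- sub("agent_genes_", "", target)
        pert <- perturb_agents(agents, fraction, direction,
          gene_pool = pool, strategy = strategy,
          importance = importance0, seed = rep_seeds[r], scope = scope
        )
        tab <- synergy_table(pert, net, importance0, similarity, decay = decay)
      } else {
        direction <- sub("edges_", "", target)
        pnet <- perturb_edges(net, fraction, direction, seed = rep_seeds[r])
        tab <- synergy_table(agents, pnet,
          importance = NULL,
          similarity = similarity, decay = decay
        )
      }
      srcc(baseline$s, tab$s)
    }, 1)
    tibble(
      target = target, fraction = fraction,
      repetition = seq_len(n_reps), srcc = srccs
    )
  })
  details <- purrr::list_rbind(details)
  report <- dplyr::summarise(
    dplyr::group_by(details, .data$target, .data$fraction),
    mean_srcc = mean(.data$srcc),
    sd_srcc = sd(.data$srcc),
    n_reps = dplyr::n(),
    .groups = "drop"
  )
  attr(report, "details") <- details
  class(report) <- c("robustness_report", class(report))
  report
}

#' @describeIn run_robustness Per-repetition SRCC values.
#' @param x A `robustness_report`.
#' @param ... Ignored.
#' @export
tidy.robustness_report <- function(x, ...) {
  attr(x, "details")
}

#' @describeIn run_robustness One-row summary across the whole report.
#' @export
glance.robustness_report <- function(x, ...) {
  tibble(
    n_settings = nrow(x),
    min_mean_srcc = min(x$mean_srcc),
    max_mean_srcc = max(x$mean_srcc)
  )
}

#' @describeIn run_robustness SRCC degradation curves by target.
#' @param object A `robustness_report`.
#' @export
autoplot.robustness_report <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$fraction, y = .data$mean_srcc,
    colour = .data$target, group = .data$target
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_srcc - .data$sd_srcc,
      ymax = .data$mean_srcc + .data$sd_srcc
    )) +
    ggplot2::labs(
      x = "perturbed fraction", y = "mean SRCC vs. unperturbed ranking",
      colour = NULL, title = "Ranking stability under perturbation"
    ) +
    ggplot2::theme_minimal()
}
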