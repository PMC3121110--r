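#' Synergy score for one agent pair
#'
#' Multiplies a topology score row and an agent score row for the same pair
#' into the synergy score `S = TS * AS`. The model assumes the two agents
#' act through independent mechanisms (Bliss independence); pairs scoring
#' above `threshold` (default 0.9) most likely act on the same gene sets,
#' contradicting that assumption, so they are flagged invalid rather than
#' ranked.
#'
#' @param ts One-row tibble from [topology_score()].
#' @param as_ One-row tibble from [agent_score()] for the same pair.
#' @param threshold Upper bound of the valid score band.
#' @return A one-row tibble: `agent_1`, `agent_2`, `ts`, `as_value`, `s`,
#'   `valid`.
#' @export
synergy_score <- function(ts, as_, threshold = 0.9) {
  if (!identical(
    pair_key(ts$agent_1, ts$agent_2),
    pair_key(as_$agent_1, as_$agent_2)
  )) {
    abort(sprintf(
      "Pair mismatch: topology score is for (%s, %s) but agent score for (%s, %s).",
      ts$agent_1, ts$agent_2, as_$agent_1, as_$agent_2
    ))
  }
  s <- ts$ts * as_$as_value
  tibble(
    agent_1 = ts$agent_1, agent_2 = ts$agent_2,
    ts = ts$ts, as_value = as_$as_value,
    s = s, valid = s <= threshold
  )
}

#' Synergy scores for all unordered agent pairs
#'
#' The workhorse behind [rank_partners()] and the robustness protocol:
#' computes TS, AS and S for every unordered pair of agents against one
#' background network.
#'
#' @param agents Agent tibble with `agent_id`, `genes` and (if `similarity`
#'   is supplied) `phenotypes` columns.
#' @param net Background network.
#' @param importance [node_importance()] for `net`; computed on the fly
#'   when `NULL`.
#' @param similarity Optional phenotype-similarity matrix; when `NULL`
#'   every AS is the neutral 1 and S reduces to TS.
#' @param decay Exponential distance-decay rate.
#' @param threshold Valid-band upper bound on S.
#' @return A tibble with one row per unordered pair: `agent_1`, `agent_2`,
#'   `ts`, `as_value`, `s`, `valid`.
#' @export
synergy_table <- function(agents, net, importance = NULL, similarity = NULL,
                          decay = 1, threshold = 0.9) {
  if (nrow(agents) < 2) {
    abort("Need at least 2 agents.")
  }
  importance <- importance %||% node_importance(net)
  ip <- as_ip(importance)
  if (!is.null(similarity)) {
    similarity <- validate_phenotype_similarity(similarity)
  }
  pre <- precompute_agent_distances(agents, net)
  idx <- which(upper.tri(diag(nrow(agents))), arr.ind = TRUE)
  rows <- purrr::map(seq_len(nrow(idx)), function(k) {
    i <- idx[k, "row"]
    j <- idx[k, "col"]
    ts <- ts_from_cache(pre, i, j, ip, decay)
    if (is.null(similarity)) {
      asv <- 1
    } else {
      asv <- agent_score(
        agents$phenotypes[[i]], agents$phenotypes[[j]], similarity,
        ids = c(agents$agent_id[i], agents$agent_id[j])
      )$as_value
    }
    tibble(
      agent_1 = agents$agent_id[i], agent_2 = agents$agent_id[j],
      ts = ts, as_value = asv
    )
  })
  out <- purrr::list_rbind(rows)
  out$s <- out$ts * out$as_value
  out$valid <- out$s <= threshold
  out
}

#' Rank candidate partner agents for a seed agent
#'
#' Scores the seed agent against every other agent and orders the valid
#' candidates by descending synergy score; ties are broken by descending
#' TS, then by partner id, so the ranking is deterministic. Pairs above the
#' validity threshold are reported after the ranked ones with rank `NA` —
#' they likely act on the same gene sets and cannot be ranked under the
#' independence assumption.
#'
#' @inheritParams synergy_table
#' @param seed_agent Id of the seed agent; must appear in `agents`.
#' @return A tibble of class `synergy_ranking` with columns `rank`, `seed`,
#'   `partner`, `ts`, `as_value`, `s`, `valid`, `meet_min`.
#' @export
rank_partners <- function(agents, seed_agent, net, importance = NULL,
                          similarity = NULL, decay = 1, threshold = 0.9) {
  if (!seed_agent %in% agents$agent_id) {
    abort(sprintf("Seed agent '%s' is not among the agents.", seed_agent))
  }
  if (nrow(agents) < 2) {
    abort("Need at least one candidate partner.")
  }
  importance <- importance %||% node_importance(net)
  ip <- as_ip(importance)
  if (!is.null(similarity)) {
    similarity <- validate_phenotype_similarity(similarity)
  }
  i <- match(seed_agent, agents$agent_id)
  pre <- precompute_agent_distances(agents, net)
  others <- setdiff(seq_len(nrow(agents)), i)
  rows <- purrr::map(others, function(j) {
    ts <- ts_from_cache(pre, i, j, ip, decay)
    asv <- if (is.null(similarity)) {
      1
    } else {
      agent_score(
        agents$phenotypes[[i]], agents$phenotypes[[j]], similarity,
        ids = c(seed_agent, agents$agent_id[j])
      )$as_value
    }
    tibble(
      seed = seed_agent, partner = agents$agent_id[j],
      ts = ts, as_value = asv,
      meet_min = meet_min(agents$genes[[i]], agents$genes[[j]])
    )
  })
  out <- purrr::list_rbind(rows)
  out$s <- out$ts * out$as_value
  out$valid <- out$s <= threshold
  out <- out[order(-out$valid, -out$s, -out$ts, out$partner), ]
  out$rank <- ifelse(out$valid, cumsum(out$valid), NA_integer_)
  out <- out[c("rank", "seed", "partner", "ts", "as_value", "s", "valid", "meet_min")]
  class(out) <- c("synergy_ranking", class(out))
  out
}

#' @describeIn rank_partners Bar chart of synergy scores by partner.
#' @param object A `synergy_ranking`.
#' @param ... Ignored.
#' @export
autoplot.synergy_ranking <- function(object, ...) {
  df <- as_tibble(object)
  df$partner <- stats::reorder(df$partner, df$s)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$s, y = .data$partner,
    fill = .data$valid
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#2c7fb8", `FALSE` = "#d95f02"),
      labels = c(`TRUE` = "valid", `FALSE` = "> threshold")
    ) +
    ggplot2::labs(
      x = "synergy score S", y = NULL, fill = NULL,
      title = sprintf("Candidate partners for %s", df$seed[1])
    ) +
    ggplot2::theme_minimal()
}

#' Meet/min gene-set overlap coefficient
#'
#' `|g1 intersect g2| / min(|g1|, |g2|)` — a network-free baseline for
#' agent-pair similarity. Reaches 1 whenever one gene set is a subset of
#' the other, and always dominates the Jaccard index.
#'
#' @param genes1,genes2 Non-empty character vectors.
#' @return A number in \[0, 1\].
#' @export
meet_min <- function(genes1, genes2) {
  g1 <- unique(genes1)
  g2 <- unique(genes2)
  if (length(g1) == 0 || length(g2) == 0) {
    abort("Gene sets must be non-empty.")
  }
  length(intersect(g1, g2)) / min(length(g1), length(g2))
}

#' GO Union-Intersection similarity of two gene sets
#'
#' Pools the GO terms annotated to each agent's genes and returns the size
#' of the intersection over the size of the union of the two pooled term
#' sets; 0 (with a warning) when neither gene set carries any annotation.
#'
#' @param genes1,genes2 Character vectors of genes.
#' @param annotations Gene-to-term annotations: a tibble with columns
#'   `gene` and `term` (see [read_go_annotations()]) or a named list of
#'   term vectors per gene. Genes without annotations contribute nothing.
#' @return A number in \[0, 1\].
#' @export
go_ui_score <- function(genes1, genes2, annotations) {
  terms_of <- function(genes) {
    if (is.data.frame(annotations)) {
      unique(annotations$term[annotations$gene %in% genes])
    } else {
      unique(unlist(annotations[intersect(names(annotations), genes)],
        use.names = FALSE
      ))
    }
  }
  t1 <- terms_of(genes1)
  t2 <- terms_of(genes2)
  u <- union(t1, t2)
  if (length(u) == 0) {
    warn("Neither gene set has GO annotations; UI score is 0.")
    return(0)
  }
  length(intersect(t1, t2)) / length(u)
}

#' Spearman rank correlation coefficient
#'
#' Rank correlation with average-rank tie handling; the statistic used
#' throughout the robustness protocol and the baseline comparisons.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A number in \[-1, 1\].
#' @export
srcc <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.")
  }
  if (length(x) < 3) {
    abort("Need at least 3 observations.")
  }
  cor(x, y, method = "spearman")
}
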