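#' Topology score for an agent pair
#'
#' The topology score TS weighs how strongly two agents' gene sets couple
#' through the background network. Writing `IP` for node importance and
#' `d(i, G)` for the minimum hop distance from gene `i` to gene set `G`,
#'
#' \deqn{TS = \frac{1}{2}\left[
#'   \frac{\sum_i IP_1(i)\, e^{-d(i, G_2)}}{\sum_i IP_1(i)} +
#'   \frac{\sum_j IP_2(j)\, e^{-d(j, G_1)}}{\sum_j IP_2(j)}\right]}
#'
#' The two bracketed terms are dual (agent 1 against agent 2's genes and
#' vice versa); each is a weighted mean of exponentially decayed proximities
#' and so lies in \[0, 1\]. Shared genes contribute `exp(0) = 1`;
#' genes in a different component contribute `exp(-Inf) = 0`. Agent genes
#' absent from the network are excluded from the computation but counted in
#' the output, so mapping failures stay visible.
#'
#' @param net Background network.
#' @param importance A [node_importance()] object computed on `net` (or a
#'   named numeric vector of IP values covering the network's nodes).
#' @param genes1,genes2 Character vectors of the two agents' genes.
#' @param decay Rate of the exponential distance decay `exp(-decay * d)`;
#'   default 1.
#' @param ids Length-2 character vector naming the pair in the output.
#' @return A one-row tibble: `agent_1`, `agent_2`, `ts`, mapped/unmapped
#'   gene counts, and a `contributions` list-column holding each mapped
#'   gene's IP weight and its minimum distance to the partner set.
#' @examples
#' net <- background_network(c("a", "b", "c", "d"), c("b", "c", "d", "e"))
#' ni <- node_importance(net)
#' topology_score(net, ni, c("a", "b"), c("d", "e"))
#' @export
topology_score <- function(net, importance, genes1, genes2, decay = 1,
                           ids = c("agent_1", "agent_2")) {
  assert_network(net)
  ip <- as_ip(importance)
  m1 <- map_genes(net, genes1, ids[1])
  m2 <- map_genes(net, genes2, ids[2])
  dmat <- igraph::distances(net, v = m1$mapped, to = m2$mapped)
  d1 <- apply(dmat, 1, min)
  d2 <- apply(dmat, 2, min)
  ip1 <- ip[m1$mapped]
  ip2 <- ip[m2$mapped]
  if (any(is.na(ip1)) || any(is.na(ip2))) {
    abort("`importance` does not cover all mapped agent genes.")
  }
  t1 <- dual_term(ip1, d1, decay, ids[1])
  t2 <- dual_term(ip2, d2, decay, ids[2])
  contributions <- dplyr::bind_rows(
    tibble(agent = ids[1], gene = m1$mapped, ip = unname(ip1), min_distance = unname(d1)),
    tibble(agent = ids[2], gene = m2$mapped, ip = unname(ip2), min_distance = unname(d2))
  )
  tibble(
    agent_1 = ids[1], agent_2 = ids[2],
    ts = (t1 + t2) / 2,
    n_mapped_1 = length(m1$mapped), n_unmapped_1 = length(m1$unmapped),
    n_mapped_2 = length(m2$mapped), n_unmapped_2 = length(m2$unmapped),
    contributions = list(contributions)
  )
}

# One bracketed term: IP-weighted mean of exp(-decay * d).
dual_term <- function(ip, d, decay, id) {
  s <- sum(ip)
  if (s == 0) {
    warn(sprintf("Agent '%s': all mapped genes have zero importance; its dual term is 0.", id))
    return(0)
  }
  w <- exp(-decay * d)
  w[!is.finite(d)] <- 0
  sum(ip * w) / s
}

as_ip <- function(importance) {
  if (inherits(importance, "node_importance")) {
    return(ip_vector(importance))
  }
  if (is.numeric(importance) && !is.null(names(importance))) {
    return(importance)
  }
  abort("`importance` must be a node_importance object or a named numeric vector.")
}

map_genes <- function(net, genes, id) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0) {
    abort(sprintf("Agent '%s' has an empty gene set.", id))
  }
  nodes <- node_ids(net)
  mapped <- intersect(genes, nodes)
  if (length(mapped) == 0) {
    abort(sprintf("Agent '%s' maps no genes into the background network.", id))
  }
  list(mapped = mapped, unmapped = setdiff(genes, nodes))
}

#' Topology-score matrix over all agent pairs
#'
#' @param agents Agent tibble with `agent_id` and `genes` columns.
#' @param net Background network.
#' @param importance [node_importance()] object for `net`.
#' @param decay Exponential decay rate, as in [topology_score()].
#' @return A symmetric numeric matrix with agent ids as dimnames; the
#'   diagonal is 1 (an agent shares all genes with itself).
#' @export
topology_score_matrix <- function(agents, net, importance, decay = 1) {
  if (nrow(agents) < 2) {
    abort("Need at least 2 agents.")
  }
  ip <- as_ip(importance)
  pre <- precompute_agent_distances(agents, net)
  n <- nrow(agents)
  out <- diag(1, n)
  dimnames(out) <- list(agents$agent_id, agents$agent_id)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out[i, j] <- out[j, i] <-
        ts_from_cache(pre, i, j, ip, decay)
    }
  }
  out
}

# Per-agent distance rows to every network node, computed once and sliced
# per pair; avoids re-running BFS for each of the O(n^2) pairs.
precompute_agent_distances <- function(agents, net) {
  assert_network(net)
  mapped <- purrr::map2(
    agents$genes, agents$agent_id,
    function(g, id) map_genes(net, g, id)$mapped
  )
  dist_rows <- purrr::map(mapped, function(g) {
    igraph::distances(net, v = g)
  })
  list(mapped = mapped, dist_rows = dist_rows)
}

ts_from_cache <- function(pre, i, j, ip, decay) {
  g1 <- pre$mapped[[i]]
  g2 <- pre$mapped[[j]]
  dmat <- pre$dist_rows[[i]][, g2, drop = FALSE]
  d1 <- apply(dmat, 1, min)
  d2 <- apply(pre$dist_rows[[j]][, g1, drop = FALSE], 1, min)
  (dual_term(ip[g1], d1, decay, "") + dual_term(ip[g2], d2, decay, "")) / 2
}
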