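#' Per-node centrality table
#'
#' Computes the three centrality measures that feed the node-importance
#' score: shortest-path betweenness (normalized by `(n-1)(n-2)/2`),
#' harmonic closeness (mean inverse distance to the other nodes, so
#' unreachable nodes contribute 0 and the value lives in \[0, 1\]), and
#' PageRank with damping 0.85. Degree can be added as an optional fourth
#' column.
#'
#' @param net Background network (undirected igraph, >= 2 nodes).
#' @param include_degree Also report raw degree (not used by
#'   [node_importance()] unless requested there).
#' @return A tibble with columns `node`, `betweenness`, `closeness`,
#'   `pagerank` (and optionally `degree`).
#' @export
compute_centralities <- function(net, include_degree = FALSE) {
  assert_network(net)
  out <- tibble(
    node = node_ids(net),
    betweenness = unname(igraph::betweenness(net, normalized = TRUE)),
    closeness = unname(igraph::harmonic_centrality(net, normalized = TRUE)),
    pagerank = unname(igraph::page_rank(net, damping = 0.85)$vector)
  )
  if (include_degree) {
    out$degree <- as.numeric(igraph::degree(net))
  }
  out
}

#' Node importance by PCA over centrality measures
#'
#' Integrates several centrality columns into a single importance score
#' `ip` per node: each column is z-score standardized (constant columns
#' become zeros), the first principal component of the standardized matrix
#' is taken, its sign is fixed so that importance increases with overall
#' centrality (positive correlation with the standardized column sums), and
#' the scores are min-max scaled to \[0, 1\]. The fraction of variance the
#' first component explains is reported; on real disease networks the three
#' measures are strongly correlated, so this fraction is typically high.
#'
#' @param x A centrality tibble (see [compute_centralities()]) with a `node`
#'   column, or a background network, in which case centralities are
#'   computed first.
#' @param measures Columns of `x` to integrate. Defaults to betweenness,
#'   harmonic closeness, and PageRank; add `"degree"` to integrate degree
#'   as well (requires the column to be present or, for networks,
#'   computes it).
#' @param ... Passed between methods.
#' @return An object of class `node_importance`: see [tidy()] for the
#'   per-node table and [glance()] for the one-row summary.
#' @examples
#' net <- background_network(c("a", "b", "c"), c("b", "c", "d"))
#' ni <- node_importance(net)
#' tidy(ni)
#' @export
node_importance <- function(x, ...) {
  UseMethod("node_importance")
}

#' @rdname node_importance
#' @export
node_importance.igraph <- function(x, measures = c("betweenness", "closeness", "pagerank"), ...) {
  cent <- compute_centralities(x, include_degree = "degree" %in% measures)
  node_importance(cent, measures = measures, ...)
}

#' @rdname node_importance
#' @export
node_importance.data.frame <- function(x, measures = c("betweenness", "closeness", "pagerank"), ...) {
  if (!"node" %in% names(x)) {
    abort("Centrality table must have a `node` column.")
  }
  missing_cols <- setdiff(measures, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Centrality column(s) not found: %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(x) < 2) {
    abort("Need centralities for at least 2 nodes.")
  }
  m <- as.matrix(x[measures])
  if (any(!is.finite(m))) {
    abort("Non-finite centrality values.")
  }
  z <- apply(m, 2, function(col) {
    s <- sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  if (all(z == 0)) {
    warn("All centrality columns are constant; IP set to 0 for every node and explained variance is undefined.")
    scores <- rep(0, nrow(x))
    ev <- NA_real_
    loadings <- stats::setNames(rep(NA_real_, length(measures)), measures)
  } else {
    pca <- prcomp(z, center = FALSE, scale. = FALSE)
    ev <- pca$sdev[1]^2 / sum(pca$sdev^2)
    scores <- pca$x[, 1]
    # Sign convention: importance must increase with overall centrality.
    overall <- rowSums(z)
    flip <- if (sd(overall) > 0) {
      cor(scores, overall) < 0
    } else {
      sum(pca$rotation[, 1]) < 0
    }
    if (flip) {
      scores <- -scores
      pca$rotation[, 1] <- -pca$rotation[, 1]
    }
    rng <- range(scores)
    scores <- if (diff(rng) == 0) rep(0, length(scores)) else (scores - rng[1]) / diff(rng)
    loadings <- stats::setNames(pca$rotation[, 1], measures)
  }
  structure(
    list(
      importance = tibble(node = x$node, ip = as.numeric(scores)),
      explained_variance = ev,
      loadings = loadings,
      measures = measures,
      centralities = as_tibble(x)
    ),
    class = "node_importance"
  )
}

#' @export
print.node_importance <- function(x, ...) {
  cat(sprintf(
    "<node_importance> %d nodes; measures: %s; PC1 explained variance: %s\n",
    nrow(x$importance), paste(x$measures, collapse = ", "),
    if (is.na(x$explained_variance)) "undefined" else sprintf("%.3f", x$explained_variance)
  ))
  print(head(dplyr::arrange(x$importance, dplyr::desc(.data$ip)), 5))
  invisible(x)
}

#' Named vector of IP values
#'
#' @param x A `node_importance` object.
#' @return Named numeric vector of importance scores in \[0, 1\].
#' @export
ip_vector <- function(x) {
  stopifnot(inherits(x, "node_importance"))
  stats::setNames(x$importance$ip, x$importance$node)
}

#' @describeIn node_importance Per-node centralities joined with `ip`.
#' @export
tidy.node_importance <- function(x, ...) {
  dplyr::left_join(x$centralities, x$importance, by = "node")
}

#' @describeIn node_importance One-row summary: node count and PC1
#'   explained variance.
#' @export
glance.node_importance <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$importance),
    n_measures = length(x$measures),
    explained_variance = x$explained_variance
  )
}

#' @describeIn node_importance Lollipop plot of the most important nodes.
#' @param object A `node_importance` object.
#' @param top_n Number of top-importance nodes to display.
#' @export
autoplot.node_importance <- function(object, top_n = 20, ...) {
  df <- dplyr::slice_max(object$importance, .data$ip, n = top_n)
  df$node <- stats::reorder(df$node, df$ip)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ip, y = .data$node)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$node), colour = "grey60") +
    ggplot2::geom_point(colour = "#2c7fb8", size = 2) +
    ggplot2::labs(
      x = "node importance (IP)", y = NULL,
      title = "Most important network nodes"
    ) +
    ggplot2::theme_minimal()
}
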