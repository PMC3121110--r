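# Brute-force reference implementations, written independently of the
# package's (igraph-backed) code paths: plain BFS over adjacency lists,
# shortest-path counting for betweenness, power iteration for PageRank.

adj_list <- function(net) {
  nodes <- igraph::V(net)$name
  el <- igraph::as_edgelist(net)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(el))) {
    adj[[el[k, 1]]] <- c(adj[[el[k, 1]]], el[k, 2])
    adj[[el[k, 2]]] <- c(adj[[el[k, 2]]], el[k, 1])
  }
  adj
}

# BFS distances and shortest-path counts from one source.
bfs_oracle <- function(adj, src) {
  nodes <- names(adj)
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  sigma <- stats::setNames(rep(0, length(nodes)), nodes)
  dist[src] <- 0
  sigma[src] <- 1
  queue <- src
  while (length(queue) > 0) {
    u <- queue[1]
    queue <- queue[-1]
    for (v in adj[[u]]) {
      if (!is.finite(dist[v])) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
      if (dist[v] == dist[u] + 1) {
        sigma[v] <- sigma[v] + sigma[u]
      }
    }
  }
  list(dist = dist, sigma = sigma)
}

oracle_distances <- function(net) {
  adj <- adj_list(net)
  nodes <- names(adj)
  out <- sapply(nodes, function(s) bfs_oracle(adj, s)$dist)
  t(out)[nodes, nodes, drop = FALSE]
}

# Normalized shortest-path betweenness via pair-dependency counting.
oracle_betweenness <- function(net) {
  adj <- adj_list(net)
  nodes <- names(adj)
  n <- length(nodes)
  bfs <- lapply(stats::setNames(nodes, nodes), function(s) bfs_oracle(adj, s))
  bc <- stats::setNames(rep(0, n), nodes)
  for (si in seq_len(n - 1)) {
    for (ti in (si + 1):n) {
      s <- nodes[si]
      t <- nodes[ti]
      dst <- bfs[[s]]$dist[t]
      if (!is.finite(dst)) next
      tot <- bfs[[s]]$sigma[t]
      for (v in setdiff(nodes, c(s, t))) {
        if (bfs[[s]]$dist[v] + bfs[[v]]$dist[t] == dst) {
          bc[v] <- bc[v] + bfs[[s]]$sigma[v] * bfs[[v]]$sigma[t] / tot
        }
      }
    }
  }
  bc / ((n - 1) * (n - 2) / 2)
}

oracle_harmonic_closeness <- function(net) {
  d <- oracle_distances(net)
  diag(d) <- NA
  rowMeans(1 / d, na.rm = TRUE)
}

oracle_pagerank <- function(net, damping = 0.85, tol = 1e-14) {
  d <- oracle_distances(net) # only for node names/order
  adj <- adj_list(net)
  nodes <- names(adj)
  n <- length(nodes)
  deg <- stats::setNames(lengths(adj), nodes)
  x <- rep(1 / n, n)
  names(x) <- nodes
  repeat {
    spread <- ifelse(deg > 0, x / deg, 0)
    xn <- stats::setNames(rep(0, n), nodes)
    for (u in nodes) {
      for (v in adj[[u]]) xn[v] <- xn[v] + spread[u]
    }
    dangling <- sum(x[deg == 0])
    xn <- (1 - damping) / n + damping * (xn + dangling / n)
    if (max(abs(xn - x)) < tol) {
      return(xn)
    }
    x <- xn
  }
}

# Direct evaluation of the topology-score formula from a distance matrix.
oracle_ts <- function(net, ip, genes1, genes2, decay = 1) {
  d <- oracle_distances(net)
  term <- function(ga, gb) {
    w <- vapply(ga, function(g) {
      dd <- min(d[g, gb])
      if (is.finite(dd)) exp(-decay * dd) else 0
    }, 1)
    sum(ip[ga] * w) / sum(ip[ga])
  }
  (term(genes1, genes2) + term(genes2, genes1)) / 2
}

oracle_as <- function(ph1, ph2, sim) {
  total <- 0
  for (p in ph1) {
    for (q in ph2) total <- total + sim[p, q]
  }
  total / (length(ph1) * length(ph2))
}

# Connected random graph: random spanning tree plus extra edges.
random_test_graph <- function(n, extra = n) {
  labels <- sprintf("n%02d", sample(n))
  from <- labels[vapply(2:n, function(i) sample.int(i - 1, 1), 1L)]
  to <- labels[2:n]
  if (extra > 0) {
    u <- labels[sample.int(n, extra, replace = TRUE)]
    v <- labels[sample.int(n, extra, replace = TRUE)]
    keep <- u != v
    from <- c(from, u[keep])
    to <- c(to, v[keep])
  }
  background_network(from, to, name = "random_test")
}

path_graph <- function(ids) {
  background_network(ids[-length(ids)], ids[-1], name = "path")
}

star_graph <- function(center, leaves) {
  background_network(rep(center, length(leaves)), leaves, name = "star")
}

cycle_graph <- function(ids) {
  background_network(ids, c(ids[-1], ids[1]), name = "cycle")
}

uniform_ip <- function(net) {
  stats::setNames(rep(1, igraph::vcount(net)), igraph::V(net)$name)
}
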