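#' Minimum shortest-path distance from a gene to a gene set
#'
#' Hop-count distance from `source` to the nearest member of `targets`;
#' 0 when `source` is itself a target, `Inf` when no target is reachable.
#' This is the distance that enters the topology score with weight
#' `exp(-d)`, so unreachable genes contribute 0.
#'
#' @param net Background network (undirected igraph).
#' @param source A single gene id present in `net`.
#' @param targets Non-empty character vector of gene ids, all present in `net`.
#' @return A single non-negative number, possibly `Inf`.
#' @export
min_distance <- function(net, source, targets) {
  assert_network(net)
  nodes <- node_ids(net)
  if (!source %in% nodes) {
    abort(sprintf("Gene '%s' is not in the network.", source))
  }
  targets <- unique(as.character(targets))
  if (length(targets) == 0) {
    abort("`targets` must be non-empty.")
  }
  missing_t <- setdiff(targets, nodes)
  if (length(missing_t) > 0) {
    abort(sprintf(
      "Target gene(s) not in the network: %s",
      paste(missing_t, collapse = ", ")
    ))
  }
  if (source %in% targets) {
    return(0)
  }
  min(igraph::distances(net, v = source, to = targets))
}

#' Collapse groups of nodes into group-level nodes
#'
#' Mirrors the two conventions for collapsing ortholog/complex groups into
#' network nodes: *keep* treats each group as a node with its member list
#' kept as-is (a gene may then sit in several group nodes), while *merge*
#' first unions any groups that share at least one member. In either mode an
#' edge joins two new nodes iff some cross-pair of their members was
#' adjacent in the input network; members referencing unknown nodes are
#' skipped with a warning.
#'
#' @param net Background network.
#' @param groups Named list mapping group id to a character vector of member
#'   node ids. Empty groups are an error.
#' @param mode `"keep"` or `"merge"`.
#' @return A new undirected igraph graph whose vertices carry a `members`
#'   list attribute with the underlying gene ids. Merged nodes are named by
#'   joining their group ids with `"+"` (sorted).
#' @export
merge_node_groups <- function(net, groups, mode = c("keep", "merge")) {
  mode <- match.arg(mode)
  assert_network(net)
  if (is.null(names(groups)) || any(names(groups) == "")) {
    abort("`groups` must be a named list of member vectors.")
  }
  if (any(lengths(groups) == 0)) {
    abort(sprintf(
      "Empty group(s): %s",
      paste(names(groups)[lengths(groups) == 0], collapse = ", ")
    ))
  }
  nodes <- node_ids(net)
  groups <- purrr::imap(groups, function(members, id) {
    members <- unique(as.character(members))
    unknown <- setdiff(members, nodes)
    if (length(unknown) > 0) {
      warn(sprintf(
        "Group '%s': skipping unknown node(s) %s",
        id, paste(unknown, collapse = ", ")
      ))
    }
    kept <- intersect(members, nodes)
    if (length(kept) == 0) {
      abort(sprintf("Group '%s' has no members in the network.", id))
    }
    kept
  })

  if (mode == "merge") {
    # Union-find over groups sharing >= 1 member.
    ids <- names(groups)
    parent <- stats::setNames(seq_along(ids), ids)
    find <- function(i) {
      while (parent[[i]] != i) i <- parent[[i]]
      i
    }
    owner <- list() # member gene -> group index
    for (i in seq_along(ids)) {
      for (g in groups[[i]]) {
        if (is.null(owner[[g]])) {
          owner[[g]] <- i
        } else {
          ri <- find(i)
          rj <- find(owner[[g]])
          if (ri != rj) parent[[ri]] <- rj
        }
      }
    }
    root <- vapply(seq_along(ids), find, 1L)
    merged <- split(seq_along(ids), root)
    groups <- purrr::map(merged, function(idx) {
      sort(unique(unlist(groups[idx], use.names = FALSE)))
    })
    names(groups) <- vapply(
      merged,
      function(idx) paste(sort(ids[idx]), collapse = "+"), ""
    )
  }

  # Edge between new nodes iff some cross-pair of members is adjacent.
  member_of <- purrr::imap(groups, function(members, id) {
    tibble(gene = members, group = id)
  })
  member_tbl <- purrr::list_rbind(member_of)
  gene_groups <- split(member_tbl$group, member_tbl$gene)
  el <- igraph::as_edgelist(net)
  new_edges <- character(0)
  for (k in seq_len(nrow(el))) {
    gu <- gene_groups[[el[k, 1]]]
    gv <- gene_groups[[el[k, 2]]]
    if (is.null(gu) || is.null(gv)) next
    for (a in gu) {
      for (b in gv) {
        if (a != b) new_edges <- c(new_edges, a, b)
      }
    }
  }
  out <- igraph::make_empty_graph(n = 0, directed = FALSE)
  out <- igraph::add_vertices(out, length(groups), name = names(groups))
  if (length(new_edges) > 0) {
    em <- matrix(new_edges, ncol = 2, byrow = TRUE)
    keep <- !duplicated(pair_key(em[, 1], em[, 2]))
    out <- igraph::add_edges(out, t(em[keep, , drop = FALSE]))
  }
  igraph::V(out)$members <- unname(groups)
  igraph::graph_attr(out, "name") <-
    paste0(igraph::graph_attr(net, "name") %||% "network", "_", mode)
  out
}

#' Extract the shortest-path subnetwork coupling two gene sets
#'
#' For each mapped gene of one set, takes all shortest paths to its
#' *nearest* genes in the other set (and vice versa) and returns the union
#' of the nodes and edges on those paths. This is the mechanism-inspection
#' view of an agent pair's joint footprint on the network target.
#'
#' @param net Background network.
#' @param genes1,genes2 Character vectors of gene ids; each must map at
#'   least one gene into `net`.
#' @return An undirected igraph subnetwork (possibly a single node when the
#'   two sets coincide in one gene).
#' @export
extract_pair_subnetwork <- function(net, genes1, genes2) {
  assert_network(net)
  nodes <- node_ids(net)
  g1 <- intersect(unique(genes1), nodes)
  g2 <- intersect(unique(genes2), nodes)
  if (length(g1) == 0 && length(g2) == 0) {
    abort("Neither gene set maps into the network.")
  }
  if (length(g1) == 0 || length(g2) == 0) {
    abort("One gene set maps no genes into the network.")
  }
  keep_nodes <- character(0)
  keep_edges <- character(0)
  collect <- function(from_set, to_set) {
    for (g in from_set) {
      shared <- g %in% to_set
      if (shared) {
        keep_nodes <<- c(keep_nodes, g)
        next
      }
      d <- igraph::distances(net, v = g, to = to_set)
      dmin <- min(d)
      if (!is.finite(dmin)) next
      nearest <- to_set[d[1, ] == dmin]
      paths <- igraph::all_shortest_paths(net, from = g, to = nearest)$vpaths
      for (p in paths) {
        ids <- igraph::V(net)$name[as.integer(p)]
        keep_nodes <<- c(keep_nodes, ids)
        if (length(ids) > 1) {
          keep_edges <<- c(keep_edges, rbind(
            ids[-length(ids)], ids[-1]
          ))
        }
      }
    }
  }
  collect(g1, g2)
  collect(g2, g1)
  keep_nodes <- unique(keep_nodes)
  out <- igraph::make_empty_graph(n = 0, directed = FALSE)
  out <- igraph::add_vertices(out, length(keep_nodes), name = keep_nodes)
  if (length(keep_edges) > 0) {
    em <- matrix(keep_edges, ncol = 2, byrow = TRUE)
    keep <- !duplicated(pair_key(em[, 1], em[, 2]))
    out <- igraph::add_edges(out, t(em[keep, , drop = FALSE]))
  }
  igraph::graph_attr(out, "name") <- "pair_subnetwork"
  out
}
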