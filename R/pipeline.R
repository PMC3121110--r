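#' End-to-end ranking pipeline over files
#'
#' Loads every input from disk, computes centralities and node importance,
#' scores the seed agent against every other agent, and writes the ranked
#' table plus the node-importance table as TSVs with a `#` metadata header
#' (tool version and a hash of the configuration, so outputs are traceable
#' and reruns byte-identical). Progress is reported to stderr; results go
#' only to files.
#'
#' @param network_path Edge-list/SIF background network file.
#' @param agents_path GMT file of agent gene sets.
#' @param seed_agent Agent id to rank partners for.
#' @param phenotypes_path Optional agent-phenotype membership TSV.
#' @param similarity_path Optional phenotype-similarity TSV (required when
#'   `phenotypes_path` is given).
#' @param go_path Optional gene-to-GO-term TSV; adds a `ui_score` column.
#' @param out_dir Output directory.
#' @param decay,threshold Scoring options, as in [rank_partners()].
#' @param seed Integer recorded in the run log (the ranking itself is
#'   deterministic).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the ranking tibble and the output paths.
#' @export
run_pipeline <- function(network_path, agents_path, seed_agent,
                         phenotypes_path = NULL, similarity_path = NULL,
                         go_path = NULL, out_dir = ".",
                         decay = 1, threshold = 0.9, seed = 1L,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) inform(sprintf(...))
  paths <- c(
    network = network_path, agents = agents_path,
    phenotypes = phenotypes_path, similarity = similarity_path,
    go = go_path
  )
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files) > 0) {
    abort(sprintf(
      "Validation failed; input file(s) not found: %s",
      paste(sprintf("%s ('%s')", names(missing_files), missing_files), collapse = ", ")
    ), class = "netsynergy_validation_error")
  }
  if (!is.null(phenotypes_path) && is.null(similarity_path)) {
    abort("`phenotypes_path` requires `similarity_path`.",
      class = "netsynergy_validation_error"
    )
  }
  if (threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1].", class = "netsynergy_validation_error")
  }

  config <- list(
    network = network_path, agents = agents_path, seed_agent = seed_agent,
    phenotypes = phenotypes_path, similarity = similarity_path, go = go_path,
    decay = decay, threshold = threshold, seed = seed
  )
  version <- as.character(utils::packageVersion("netsynergy"))
  stamp <- sprintf(
    "netsynergy %s; config_hash=%s; seed=%d",
    version, rlang::hash(config), as.integer(seed)
  )

  say("[load] reading inputs")
  net <- read_network(network_path, quiet = quiet)
  agents <- read_agents(agents_path)
  similarity <- NULL
  if (!is.null(similarity_path)) {
    similarity <- read_phenotype_similarity(similarity_path)
    if (!is.null(phenotypes_path)) {
      agents <- add_phenotypes(agents, read_phenotype_membership(phenotypes_path))
    }
  }

  say("[importance] centralities and PCA integration")
  importance <- node_importance(net)
  say(
    "[importance] PC1 explained variance: %s",
    format(importance$explained_variance, digits = 4)
  )

  say("[rank] scoring %d candidate partners for '%s'", nrow(agents) - 1, seed_agent)
  ranking <- rank_partners(agents, seed_agent, net, importance, similarity,
    decay = decay, threshold = threshold
  )
  if (!is.null(go_path)) {
    ann <- read_go_annotations(go_path)
    gene_sets <- stats::setNames(agents$genes, agents$agent_id)
    ranking$ui_score <- purrr::map_dbl(
      ranking$partner,
      function(p) go_ui_score(gene_sets[[seed_agent]], gene_sets[[p]], ann)
    )
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- c(
    ranking = file.path(out_dir, "ranking.tsv"),
    importance = file.path(out_dir, "node_importance.tsv"),
    log = file.path(out_dir, "run_log.txt")
  )
  write_stamped_tsv(as_tibble(ranking), out[["ranking"]], stamp)
  write_stamped_tsv(tidy(importance), out[["importance"]], stamp)
  writeLines(c(
    stamp,
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("input %s sha=%s", names(paths), vapply(paths, file_hash, "")),
    sprintf(
      "network nodes=%d edges=%d; agents=%d",
      igraph::vcount(net), igraph::ecount(net), nrow(agents)
    )
  ), out[["log"]])
  say("[done] wrote %s", out[["ranking"]])
  invisible(list(ranking = ranking, importance = importance, paths = out))
}

write_stamped_tsv <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", stamp), con)
  utils::write.table(df, con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

file_hash <- function(path) {
  rlang::hash(readLines(path, warn = FALSE))
}
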