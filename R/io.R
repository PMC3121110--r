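#' Read a background network from an edge list or SIF file
#'
#' The background network is the disease-specific gene network against which
#' agent pairs are scored. Both accepted formats are line-oriented text:
#' a 2-column tab/space-separated edge list (`nodeA nodeB`), or SIF
#' (`nodeA relation nodeB`, relation ignored). Lines starting with `#` and
#' blank lines are skipped. Self-loops are dropped with a warning and
#' duplicate edges (in either orientation) are collapsed.
#'
#' @param path Path to the network file.
#' @param format `"auto"` (default; 3 fields on the first data line means
#'   SIF), `"edgelist"`, or `"sif"`.
#' @param name Label stored as the graph's `name` attribute.
#' @param quiet Suppress the node/edge count message.
#' @return An undirected, simple [igraph][igraph::igraph-package] graph whose
#'   vertex names are the gene identifiers.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("a\tb", "b\tc", "b\tc"), tf)
#' net <- read_network(tf)
#' igraph::vcount(net) # 3
#' @export
read_network <- function(path, format = c("auto", "edgelist", "sif"),
                         name = NULL, quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("Network file not found: '%s'", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) {
    abort(sprintf("Network file '%s' contains no edges.", path))
  }
  fields <- strsplit(trimws(lines[rows]), "[\t ]+")
  nf <- lengths(fields)
  if (format == "auto") {
    format <- if (nf[1] >= 3) "sif" else "edgelist"
  }
  min_fields <- if (format == "sif") 3L else 2L
  bad <- which(nf < min_fields)
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed %s line %d in '%s': expected at least %d fields, found %d.",
      format, rows[bad[1]], path, min_fields, nf[bad[1]]
    ))
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", if (format == "sif") 3L else 2L)
  net <- background_network(from, to, name = name %||% basename(path))
  if (!quiet) {
    inform(sprintf(
      "Loaded network '%s': %d nodes, %d edges.",
      igraph::graph_attr(net, "name"), igraph::vcount(net), igraph::ecount(net)
    ))
  }
  net
}

#' Build a background network from endpoint vectors
#'
#' Deduplicates unordered edges and drops self-loops (with a warning), the
#' same normalization [read_network()] applies to files.
#'
#' @param from,to Character vectors of equal length naming edge endpoints.
#' @param name Label stored as the graph's `name` attribute.
#' @return An undirected simple igraph graph.
#' @export
background_network <- function(from, to, name = "network") {
  from <- as.character(from)
  to <- as.character(to)
  stopifnot(length(from) == length(to))
  loops <- from == to
  if (any(loops)) {
    warn(sprintf("Dropped %d self-loop(s).", sum(loops)))
    from <- from[!loops]
    to <- to[!loops]
  }
  if (length(from) == 0) {
    abort("No edges remain after dropping self-loops.")
  }
  keep <- !duplicated(pair_key(from, to))
  net <- igraph::graph_from_edgelist(cbind(from[keep], to[keep]),
    directed = FALSE
  )
  igraph::graph_attr(net, "name") <- name
  net
}

#' Write a network as a 2-column TSV edge list
#'
#' @param net An undirected igraph graph.
#' @param path Output path.
#' @param header Optional character vector written as `#`-prefixed comment
#'   lines before the edges.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, header = NULL) {
  assert_network(net)
  el <- igraph::as_edgelist(net)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", header), con)
  }
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), con)
  invisible(path)
}

#' Read agent gene sets from a GMT file
#'
#' GMT is the standard multi-gene-set exchange format: one agent per line,
#' tab-separated fields `agent_id`, `description`, then gene ids. Duplicate
#' genes within a line are deduplicated; duplicate agent ids across lines
#' are an error, as is a line with no genes.
#'
#' @param path Path to the GMT file.
#' @return A tibble with one row per agent: `agent_id`, `description`,
#'   `genes` (list-column of character vectors), and an empty `phenotypes`
#'   list-column to be filled by [add_phenotypes()] or
#'   [derive_agent_phenotypes()].
#' @export
read_agents <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Agent GMT file not found: '%s'", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0) {
    abort(sprintf("Agent file '%s' is empty.", path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 2) {
      abort(sprintf(
        "Malformed GMT line %d: expected agent_id, description and >= 1 gene.", i
      ))
    }
    genes <- unique(f[-(1:2)])
    genes <- genes[genes != ""]
    if (length(genes) == 0) {
      abort(sprintf("GMT line %d ('%s') has zero genes.", i, f[[1]]))
    }
    rows[[i]] <- tibble(agent_id = f[[1]], description = f[[2]], genes = list(genes))
  }
  out <- purrr::list_rbind(rows)
  dup <- out$agent_id[duplicated(out$agent_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate agent_id in '%s': %s", path, paste(unique(dup), collapse = ", ")))
  }
  out$phenotypes <- rep(list(character()), nrow(out))
  out
}

#' Write agent profiles as GMT
#'
#' @param agents Agent tibble as returned by [read_agents()] or
#'   [simulate_scenario()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agents <- function(agents, path) {
  desc <- agents$description %||% rep("-", nrow(agents))
  lines <- purrr::pmap_chr(
    list(agents$agent_id, desc, agents$genes),
    function(id, d, g) paste(c(id, d, g), collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an agent-to-phenotype membership table
#'
#' A 2-column TSV (`agent_id`, `phenotype_id`); a header line is detected
#' and skipped if its first field is literally `agent_id`.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `agent_id` and `phenotype_id`.
#' @export
read_phenotype_membership <- function(path) {
  df <- utils::read.table(path,
    sep = "\t", header = FALSE, comment.char = "#",
    col.names = c("agent_id", "phenotype_id"), colClasses = "character"
  )
  if (nrow(df) > 0 && df$agent_id[1] == "agent_id") {
    df <- df[-1, , drop = FALSE]
  }
  as_tibble(df)
}

#' Attach phenotype sets to agent profiles
#'
#' @param agents Agent tibble (see [read_agents()]).
#' @param membership Tibble with columns `agent_id`, `phenotype_id`.
#' @return `agents` with its `phenotypes` list-column filled; agents absent
#'   from `membership` keep an empty phenotype set.
#' @export
add_phenotypes <- function(agents, membership) {
  split_ph <- split(membership$phenotype_id, membership$agent_id)
  agents$phenotypes <- purrr::map(
    agents$agent_id,
    function(id) unique(as.character(split_ph[[id]] %||% character()))
  )
  agents
}

#' Read a phenotype-similarity matrix
#'
#' A square TSV with a header row and first column of phenotype ids;
#' values must lie in \[0, 1\], the matrix must be symmetric and its
#' diagonal 1 (the similarity of a phenotype with itself).
#'
#' @param path Path to the TSV.
#' @param tol Symmetry tolerance forwarded to [validate_phenotype_similarity()].
#' @return A validated numeric matrix with phenotype ids as dimnames.
#' @export
read_phenotype_similarity <- function(path, tol = 1e-8) {
  m <- as.matrix(utils::read.table(path,
    sep = "\t", header = TRUE,
    row.names = 1, check.names = FALSE, comment.char = "#"
  ))
  validate_phenotype_similarity(m, tol = tol)
}

#' Validate a phenotype-similarity matrix
#'
#' @param m Square numeric matrix with identical row and column names.
#' @param tol Maximum allowed asymmetry `max|P - t(P)|`.
#' @return `m` (symmetrized to machine precision), invisibly usable downstream.
#' @export
validate_phenotype_similarity <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("Phenotype similarity must be a square matrix.")
  }
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    abort("Phenotype similarity must carry identical row and column names.")
  }
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1)) {
    abort("Phenotype similarity entries must be finite values in [0, 1].")
  }
  if (max(abs(m - t(m))) > tol) {
    abort(sprintf("Phenotype similarity is asymmetric beyond tolerance %g.", tol))
  }
  if (any(abs(diag(m) - 1) > tol)) {
    abort("Phenotype similarity diagonal must be 1.")
  }
  (m + t(m)) / 2
}

#' Write a phenotype-similarity matrix as TSV
#'
#' @param m Similarity matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_similarity <- function(m, path) {
  df <- data.frame(phenotype = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a dose-response inhibition table
#'
#' Expected TSV columns: `dose1`, `dose2` (doses of the two agents at a
#' fixed ratio), `ir1`, `ir2` (single-agent inhibition rates) and
#' `ir_combo` (observed combination inhibition rate). Rates given as
#' percentages (any value > 1) are converted to fractions with a warning.
#'
#' @param path Path to the TSV.
#' @return A tibble suitable for [miir()].
#' @export
read_dose_response <- function(path) {
  df <- as_tibble(utils::read.table(path,
    sep = "\t", header = TRUE,
    comment.char = "#"
  ))
  need <- c("dose1", "dose2", "ir1", "ir2", "ir_combo")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Dose-response table lacks column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  df[c("ir1", "ir2", "ir_combo")] <- ir_columns(df)
  df
}

#' Read a gene-to-GO-term annotation table
#'
#' A 2-column TSV (`gene`, `term`), header detected as in
#' [read_phenotype_membership()].
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene` and `term`.
#' @export
read_go_annotations <- function(path) {
  df <- utils::read.table(path,
    sep = "\t", header = FALSE, comment.char = "#",
    col.names = c("gene", "term"), colClasses = "character"
  )
  if (nrow(df) > 0 && df$gene[1] == "gene") {
    df <- df[-1, , drop = FALSE]
  }
  as_tibble(df)
}
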