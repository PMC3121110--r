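#' Agent score: mean phenotype similarity of two agents
#'
#' AS is the mean similarity over all cross pairs of the two agents'
#' phenotypes, `AS = sum(P[i, j]) / N` with `N = |ph1| * |ph2|`, where `P`
#' is a phenotype-similarity matrix with entries in \[0, 1\]. Phenotypes not
#' covered by the matrix are dropped with a warning; when either agent has
#' no covered phenotype, AS falls back to the neutral value 1 (so the
#' synergy score degrades gracefully to the topology score) and the
#' corresponding missing-phenotype flag is set.
#'
#' @param phenotypes1,phenotypes2 Character vectors of the two agents'
#'   phenotype ids.
#' @param similarity Phenotype-similarity matrix (see
#'   [read_phenotype_similarity()]); validated for symmetry before use.
#' @param ids Length-2 character vector naming the pair in the output.
#' @param tol Symmetry tolerance for validation.
#' @return A one-row tibble: `agent_1`, `agent_2`, `as_value`, `n_pairs`,
#'   `missing_phenotype_1`, `missing_phenotype_2`.
#' @export
agent_score <- function(phenotypes1, phenotypes2, similarity,
                        ids = c("agent_1", "agent_2"), tol = 1e-8) {
  similarity <- validate_phenotype_similarity(similarity, tol = tol)
  ph1 <- cover_phenotypes(phenotypes1, similarity, ids[1])
  ph2 <- cover_phenotypes(phenotypes2, similarity, ids[2])
  miss1 <- length(ph1) == 0
  miss2 <- length(ph2) == 0
  if (miss1 || miss2) {
    return(tibble(
      agent_1 = ids[1], agent_2 = ids[2],
      as_value = 1, n_pairs = 0L,
      missing_phenotype_1 = miss1, missing_phenotype_2 = miss2
    ))
  }
  tibble(
    agent_1 = ids[1], agent_2 = ids[2],
    as_value = mean(similarity[ph1, ph2, drop = FALSE]),
    n_pairs = length(ph1) * length(ph2),
    missing_phenotype_1 = FALSE, missing_phenotype_2 = FALSE
  )
}

cover_phenotypes <- function(ph, similarity, id) {
  ph <- unique(as.character(ph))
  covered <- intersect(ph, rownames(similarity))
  dropped <- setdiff(ph, covered)
  if (length(dropped) > 0) {
    warn(sprintf(
      "Agent '%s': phenotype(s) not covered by the similarity matrix dropped: %s",
      id, paste(dropped, collapse = ", ")
    ))
  }
  covered
}

#' Derive an agent's phenotypes from phenotype gene sets
#'
#' A phenotype belongs to an agent when its gene set intersects the agent's
#' genes; this is how OMIM-style phenotype records are attached to an agent
#' when no explicit membership table is available.
#'
#' @param genes Character vector of the agent's genes.
#' @param phenotype_gene_sets Named list mapping phenotype id to a gene set.
#' @return Character vector of phenotype ids (possibly empty).
#' @export
derive_agent_phenotypes <- function(genes, phenotype_gene_sets) {
  if (length(phenotype_gene_sets) == 0) {
    abort("`phenotype_gene_sets` must be non-empty.")
  }
  hits <- purrr::map_lgl(phenotype_gene_sets, function(g) {
    length(intersect(genes, g)) > 0
  })
  names(phenotype_gene_sets)[hits]
}

#' Derive phenotypes for every agent in a profile table
#'
#' @param agents Agent tibble with `agent_id` and `genes` columns.
#' @param phenotype_gene_sets Named list mapping phenotype id to a gene set.
#' @return `agents` with its `phenotypes` list-column replaced by the
#'   derived sets.
#' @export
derive_phenotypes <- function(agents, phenotype_gene_sets) {
  agents$phenotypes <- purrr::map(
    agents$genes, derive_agent_phenotypes,
    phenotype_gene_sets = phenotype_gene_sets
  )
  agents
}
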