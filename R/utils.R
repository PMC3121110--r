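# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's rounding).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Number of elements touched by a perturbation: round(fraction * count),
# half away from zero, but at least 1 whenever fraction > 0.
n_perturbed <- function(fraction, count) {
  if (fraction < 0 || fraction > 1) {
    abort("`fraction` must be a proportion in [0, 1].")
  }
  if (fraction == 0) {
    return(0L)
  }
  max(1L, as.integer(round_half_away(fraction * count)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. `seed = NULL` uses the
# current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive n reproducible child seeds from one master seed, so repetitions
# are independent draws yet the whole run is replayable.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# sample() without the length-1 surprise (sample(5L) permutes 1:5).
sample_from <- function(x, size) {
  x[sample.int(length(x), size)]
}

assert_network <- function(net, arg = "net") {
  if (!igraph::is_igraph(net)) {
    abort(sprintf("`%s` must be an igraph object (see `read_network()`).", arg))
  }
  if (igraph::is_directed(net)) {
    abort(sprintf("`%s` must be undirected.", arg))
  }
  if (igraph::vcount(net) < 2) {
    abort(sprintf("`%s` must have at least 2 nodes.", arg))
  }
  invisible(net)
}

node_ids <- function(net) {
  igraph::V(net)$name
}

# Canonical unordered pair label, used for symmetry-safe joins.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
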