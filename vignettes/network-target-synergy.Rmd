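---
title: "Network-target synergy scoring: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-target synergy scoring: model, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsynergy)
```

## The model

`netsynergy` ranks pairs of pharmacological agents by how plausibly they
act synergistically on a disease process, using only three inputs: an
undirected background network of disease-relevant genes, each agent's set
of affected genes, and a phenotype-similarity matrix. The underlying
assumption is that synergy between independently acting agents shows up
as a *network* relationship between their molecular footprints: the genes
of a synergistic pair should (a) occupy topologically important positions
in the disease network and (b) lie close to each other on it — the
configuration in which two independent mechanisms converge on shared
complexes, pathway crosstalk, or feedback loops.

Three quantities implement this:

**Node importance.** Betweenness, harmonic closeness and PageRank all
measure "importance" but on incommensurate scales. We z-score each
column and take the first principal component of the resulting matrix as
a single integrated importance axis; on networks with heavy-tailed
degree distributions the three measures are strongly collinear, so this
component typically captures well over half of their variance (the
`explained_variance` field reports the fraction, and a property test
holds it above 0.6 on simulated scale-free networks of 200+ nodes). The
component's sign is arbitrary in PCA, so we orient it to correlate
positively with the standardized column sums — importance must increase
with centrality — and min–max scale to [0, 1] so the scores can serve
as non-negative weights.

**Topology score.** For gene sets $G_1, G_2$ with importance $IP$:

$$TS = \frac{1}{2}\left[
  \frac{\sum_{i \in G_1} IP_1(i)\,e^{-d(i, G_2)}}{\sum_{i \in G_1} IP_1(i)} +
  \frac{\sum_{j \in G_2} IP_2(j)\,e^{-d(j, G_1)}}{\sum_{j \in G_2} IP_2(j)}
\right]$$

where $d(i, G)$ is the minimum hop count from gene $i$ to set $G$. Each
bracketed term is a weighted mean of values in [0, 1], so $TS \in [0, 1]$
and the two dual terms make it symmetric in the pair. Normalizing each
term by its own $\sum IP$ and averaging the two is a deliberate choice:
an unnormalized sum would grow with gene-set size and be unbounded,
whereas a bounded score can be compared across pairs and combined
multiplicatively with the agent score.

**Agent score and the synergy score.** $AS$ is the mean phenotype
similarity over the full cross product of the two agents' phenotype sets
($N = |ph_1| \cdot |ph_2|$ pairs). We average over *all* cross pairs
rather than best matches: the similarity matrix is itself a soft measure,
and a best-match rule would let a single spurious high entry dominate.
$S = TS \times AS$, and pairs with $S > 0.9$ are flagged invalid: a score
that high essentially requires near-identical gene sets, which
contradicts the independent-mechanism assumption the score is built on
(the same reason the Bliss independence model, not Loewe additivity,
backs the experimental readout below). Invalid pairs are reported but
excluded from rank positions.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `decay` | 1 | rate of the exponential distance decay $e^{-\text{decay}\,d}$; hop counts are unitless, and unit rate is the minimal reading of "negative exponential". Larger values localize the score. |
| PageRank damping | 0.85 | the canonical value; the background network is undirected and unweighted. |
| `threshold` | 0.9 | upper bound of the valid score band (see above). |
| `measures` | betweenness, closeness, pagerank | degree can be added as a fourth column (`measures = c(..., "degree")`); it is largely redundant with PageRank on undirected graphs, which is why it is optional. |
| perturbation `fraction` | — | a proportion in [0, 1]; the protocol's canonical schedule moves in steps of 0.1. |

## Numerical conventions and degenerate inputs

* Distances are unweighted hop counts; a gene shared by both sets has
  $d = 0$ and contributes $e^0 = 1$ (maximal coupling). Genes in a
  different component have $d = \infty$ and contribute 0 — disconnected
  genes cannot couple through the network.
* Agent genes absent from the background network are excluded from TS
  but counted and reported (`n_unmapped_*`); silently dropping them would
  hide mapping failures. How the original screen handled unmapped genes
  is not documented anywhere we know of; report-and-exclude is the
  conservative choice.
* An agent whose mapped genes all have zero importance contributes a
  zero dual term, with a warning.
* Constant centrality columns z-score to zeros; if *all* columns are
  constant, every IP is 0 and the explained variance is reported as `NA`
  with a warning (there is no variance to explain).
* An agent with no phenotypes covered by the similarity matrix gets the
  neutral $AS = 1$ plus a flag, so $S$ degrades to $TS$ instead of
  zeroing a possibly valid pair.
* Ranking ties break by descending TS, then partner id — rankings are
  deterministic and reruns byte-identical.
* Perturbation counts are `round(fraction * n)` half-away-from-zero,
  with a minimum of 1 whenever `fraction > 0`, so a nominal perturbation
  never silently becomes a no-op.
* The Spearman correlations throughout use average ranks for ties
  (`stats::cor(method = "spearman")`).

## The robustness protocol

`run_robustness()` perturbs agent genes (add/remove, default 100
repetitions) or network edges (default 20 repetitions) at given
fractions, recomputes all pairwise synergy scores, and summarizes each
setting by the mean ± sd Spearman correlation against the unperturbed
scores. A master seed spawns per-repetition child seeds, so runs are
reproducible without correlated draws. Gene perturbations are applied to
all agents simultaneously per repetition (the alternative — one agent at
a time — is available via `scope = "single"`; we default to simultaneous
perturbation because it models uniform annotation noise rather than a
single mis-curated agent). Removal can be random or targeted at each
agent's highest-IP genes (`strategy = "top_ip"`): on scale-free networks
the ranking tolerates substantial random edge deletion but degrades
sharply when key genes are removed, the behaviour expected of power-law
topologies, and the acceptance suite asserts exactly this ordering.

## Bliss independence and MIIR

For a fixed-ratio dose series, the additive expectation for two
independent inhibitors is $IR_{add} = IR_1 + IR_2 - IR_1 IR_2$, and the
experimental synergy readout is $MIIR = \max_d (IR_{syn} - IR_{add})$,
which may be negative for sub-additive pairs. Whether the maximum should
be restricted to *effective* doses (combination inhibition strictly
above 70%) is ambiguous in practice; both modes are provided and the
default is unrestricted. The effectiveness cutoff is a strict
inequality. Rates supplied as percentages are auto-detected (any value
above 1) and converted with a warning.

## What the synthetic generator emulates — and what it does not

`simulate_scenario()` produces every input the pipeline consumes. Its
defaults are the conditions the method was developed under: a 2707-node
scale-free background network (preferential attachment, 3 edges per new
node, giving ~8100 edges — the density of a curated disease network),
63 agents with gene counts uniform on 10–108, and a 50-phenotype
similarity matrix in 5 blocks (0.7 within, 0.1 between, Gaussian jitter
0.03) with 3 phenotypes per agent — the block structure stands in for
disease families, so same-disease agents score a high AS. Placement
policies put agent genes on hubs (top-decile degree — in a scale-free
graph these are both important and mutually close), in peripheral
low-degree neighbourhoods, in arbitrary local modules, or uniformly at
random; a `pairing` vector makes chosen agents share both their network
neighbourhood and their phenotype block, planting a synergistic pair
whose recovery the tests measure.

What it does *not* emulate: literature-derived annotation bias (real
agent gene sets are enriched for well-studied genes), correlated errors
between the network and the gene sets (both curated from the same
literature), weighted or directed interactions, and realistic phenotype
similarity (which comes from text mining, not clean blocks). Passing the
planted-recovery tests therefore shows that the score separates
network-adjacent-important from distant-peripheral footprints under
controlled conditions — not that it reproduces any particular curated
screen.

`simulate_dose_response()` plants a known MIIR as a localized bump on
top of the Bliss expectation of two monotone Hill curves with plateau
0.75 (single agents rarely reach complete inhibition, and the sub-unit
plateau leaves headroom so the planted bump is recovered exactly in the
noiseless case).

## Problem sizes in the test suite

The suite runs oracle comparisons (hand-written BFS, path counting,
power iteration) on graphs up to 30 nodes, planted-synergy recovery on
100 seeded 250-node scenarios, and the robustness ordering on one
500-node, 10-agent context with 20 repetitions; the acceptance script
adds one full-scale screen (2707 nodes, 63 agents, 1953 pairs). These
sizes give stable statistics while keeping a full run in tens of
seconds; all of them are choices of this package, not of the method.

## Known limitations

* The score does not distinguish synergy from antagonism; a
  high-scoring pair is a candidate for interaction, not a guaranteed
  positive interaction.
* Networks are undirected and unweighted; directed centralities and
  edge confidence weights are out of scope.
* Combinations of more than two agents are supported only by pooling a
  mixture's genes into one agent profile.
* The exact scaling of the original screen's printed scores is not
  reproducible from its description (its IP scaling and sign conventions
  are unstated), so cross-study comparisons should use ranks, not raw
  score magnitudes.
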