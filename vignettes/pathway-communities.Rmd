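---
title: "Pathway communities: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway communities: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcomm)
```

## The model

`pathcomm` treats a collection of gene sets as a weighted undirected
graph. The node set is the pathways; the edge weight between pathways
$i$ and $j$ is derived from the one-sided Fisher's exact test on their
gene overlap. With gene sets $A$ and $B$ in a universe of $N$ genes and
$k = |A \cap B|$,

$$p_{ij} = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, |A|, |B|),$$

the upper tail of the hypergeometric distribution. Only enrichment is
tested: a *depleted* overlap carries no similarity information, so the
lower tail is never used. The $\binom{n}{2}$ p-values are Bonferroni
corrected, pairs with corrected $p > \alpha$ (default $0.01$) receive
weight zero, and surviving pairs get $w_{ij} = -\log_{10} p_{\mathrm{corr}}$,
capped at 300. The assumptions worth keeping in mind:

* overlaps between different pathway pairs are treated as independent
  tests (they are not, strictly — pathways share genes — but the
  Bonferroni family-wise bound is conservative under any dependence);
* the universe matters: a smaller background inflates overlap
  significance. The default universe is the union of all genes in the
  loaded collection, the only background computable from the input
  alone; an explicit background (e.g. all assayed genes) can be given to
  `geneset_collection()` or via `--universe` and is the better choice
  when available.

Communities are found by maximizing weighted modularity

$$Q = \sum_c \left[ \frac{\Sigma_{in}(c)}{2m}
      - \gamma \left( \frac{\Sigma_{tot}(c)}{2m} \right)^{\!2} \right]$$

with a native two-phase Louvain optimizer: seeded, shuffled single-node
moves to the neighbouring community with the largest gain, then
aggregation with self-loops, iterated to convergence. The resolution
$\gamma$ scales only the null-model term; it is the one knob that
controls granularity.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.01 | threshold on the (corrected) overlap p-value; pairs above it get weight 0 |
| `weight_cap` | 300 | upper bound on $-\log_{10} p$ (dimensionless); keeps underflowed p-values finite |
| `threshold_on` | `"corrected"` | which p-value the threshold applies to |
| `resolution` | 0.4 | modularity resolution $\gamma$; 0.4 yields coarse, database-spanning communities on dense overlap networks, $\gamma = 1$ is classical modularity |
| `seed`, `restarts` | 1, 1 | node-visit-order seed; restarts rerun with consecutive seeds and keep the best-$Q$ partition |
| `min_count` (labelling) | 3 | minimum member support for an n-gram label |
| `alpha` (over-representation) | 0.05 | threshold on BH-adjusted p-values |

## Decisions where the design was open

Several choices were genuinely open; the package picks one, exposes the
alternative where reasonable, and records the choice here.

* **Threshold on raw vs corrected p.** The corrected p-value is both
  thresholded and log-transformed, so one quantity drives the edge
  entirely; `threshold_on = "raw"` exposes the looser variant for
  sensitivity analyses.
* **Bonferroni family for the graph** is the number of unordered
  pathway pairs (the tests actually performed). For a *query*, the
  family is the number of pathways — the family a user running that
  enrichment screen faces — and the query's temporary edges follow the
  graph's own threshold rule so its ΔQ values are commensurate with the
  stored weights.
* **Hubness** is the node's weighted degree inside the induced subgraph
  of its own community: the simplest centrality consistent with "hub"
  usage; it feeds the labelling tie-break and community views.
* **NMI normalization** is the arithmetic mean of the entropies
  (`normalization =` `"min"`, `"max"`, `"geometric"` are available).
  Degenerate conventions: two single-cluster labellings score 1, exactly
  one zero-entropy labelling scores 0.
* **Overlap-fraction denominator** is the focal pathway's own size, so a
  pathway fully contained in another scores 1 regardless of the
  partner's size; this reads as "what fraction of *this* pathway is
  redundant".
* **Stop words.** The shipped list is standard English plus a few
  connectives; domain words such as *pathway*, *process* and
  *regulation* are deliberately kept because GO/REACTOME names use them
  contrastively. The list is a plain-text file and fully replaceable.
* **Label fallback** extends past 2-mers to 1-mers and finally to
  unfloored 1-mers: small communities can fail the 3-appearance floor at
  every order, and an unlabelled community is less useful than a weakly
  supported one-word label.
* **ΔQ tie-breaks** during node moves keep the current community; among
  new communities with equal gain the lowest id wins. Both rules exist
  purely for determinism under a fixed seed.

## Numerical choices

* All tail probabilities are computed in log space
  (`phyper(log.p = TRUE)`), so p-values around $10^{-300}$ and below do
  not underflow before the weight is formed; the cap handles the rest.
  The two set sizes are put in canonical (min, max) order first, making
  the p-value exactly symmetric in its arguments at the bit level.
* A Louvain pass stops when no move improves $Q$ by more than
  $10^{-12}$ — a float-noise guard that prevents infinite cycling on
  plateaus.
* Partitions are relabelled canonically (community 0 largest, ties by
  smallest member id) so that runs are comparable and exports stable.
* Edgeless graphs make modularity undefined; `modularity_score()` and
  `louvain()` refuse them rather than returning 0/0. Isolated nodes are
  kept and become singleton communities.
* Exported weights are printed with 15 significant digits; re-importing
  an edge TSV reproduces the graph to the last bit.

## The synthetic generator

`synthetic_spec()` plants $K$ pairwise-disjoint community gene pools
plus a shared background. Each pathway draws
`round(within_fraction * set_size)` genes from its own pool and the rest
from the background; names are a database tag, a community-specific
contiguous 3-token core, and a unique suffix; a category map carries the
planted truth. Defaults — $K = 5$, 20 pathways per community, 200-gene
pools, 2000 background genes, 40-gene sets, `within_fraction = 0.8`,
seed 7 — give a 100-pathway collection whose graph is strongly
modular but not trivially disconnected. `within_fraction` is the single
difficulty knob: 1.0 disconnects the communities entirely, values near
$1/K$ erase the structure.

What the generator emulates: community-structured overlap, multiple
source databases, recoverable naming signal. What it does **not**
emulate: real collections' heavy-tailed set-size distributions, nested
GO hierarchies, genuinely shared biology between categories, or
inconsistent naming conventions. Passing recovery tests therefore shows
the machinery is correct and well-calibrated on clean planted structure;
it does not certify any particular NMI on real databases, where curated
categories are themselves noisy labels.

Test problem sizes are deliberately modest — 100-pathway collections,
8-node graphs for exhaustive-search comparisons (4140 partitions),
hypergeometric oracle sweeps up to $N = 30$ — chosen so the full suite
re-derives every expected value from first principles in seconds.

## Known limitations

* **Louvain is greedy.** It cannot split a community formed at an
  earlier level, so some global optima are unreachable under any visit
  order. On random 8-node weighted graphs the suite measures how often
  the exhaustive-search optimum is attained; a small fraction of
  instances land in the same local optima that other Louvain
  implementations (e.g. igraph's) also land in. Restarts mitigate but do
  not eliminate this; for pathway-scale networks the affected gaps are
  small relative to $Q$.
* **The query holds the partition fixed.** A query never reshapes
  communities; a gene set genuinely spanning two communities gets a
  ranking, not a merged view.
* **Labels inherit naming conventions.** The n-gram labeller can only
  surface what member names contain; cryptic or inconsistent naming
  yields weak labels (the ranked candidate list, not just the top item,
  is exported for this reason).
* **Bonferroni over all pairs is conservative** for large collections;
  edges near the threshold are the first to disappear as collections
  grow. The threshold, cap and correction family are all explicit
  parameters so this behaviour is inspectable.
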