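# pathcomm

Pathway databases (KEGG, REACTOME, GO) are heavily redundant: the same
biological process appears under many names, with overlapping but
inconsistent gene memberships, within and across databases. `pathcomm`
reconciles a collection of gene sets into **communities of related
pathways** by building a weighted pathway-similarity network and applying
modularity-based community detection, then labels each community
automatically from member pathway names and lets you **query novel gene
sets** against the learned community structure. It is aimed at
computational biologists who run pathway enrichment and want results
grouped by function rather than scattered over hundreds of near-duplicate
gene sets.

## Method

**Network construction.** For every pair of pathways *(i, j)* with gene
sets *A*, *B* in a universe of *N* genes, the one-sided Fisher's exact
test gives the probability of their overlap under a hypergeometric null:

    p_ij = P(X >= |A ∩ B|),   X ~ Hypergeom(N, |A|, |B|)

p-values are Bonferroni-corrected over all n(n−1)/2 pairs; pairs with
corrected p > 0.01 get weight 0, the rest get edge weight
w_ij = −log10(p_corrected), capped at 300. The result is a sparse
weighted graph whose edges encode significant gene sharing.

**Community detection.** A native Louvain implementation greedily
maximizes weighted modularity with a resolution parameter γ
(default 0.4):

    Q = Σ_c [ Σ_in(c)/2m − γ (Σ_tot(c)/2m)² ]

where Σ_in(c) is twice the intra-community edge weight, Σ_tot(c) the sum
of member degrees, and m the total edge weight. Node visit order is
seeded; restarts across consecutive seeds return the best-Q partition.

**Labelling.** Member pathway names are tokenized (database identifiers
and stop words removed) and contiguous token 3-mers counted across
members; the most common 3-mer with at least 3 appearances is the label,
with ties broken by the mean intra-community hubness of the supporting
pathways, falling back to 2-mers (then 1-mers) when nothing qualifies.

**Querying.** A new gene set is scored against every pathway (Bonferroni
over the number of pathways), temporarily added to the graph with edges
weighted exactly as in construction, and — holding the learned partition
fixed — the modularity change ΔQ of moving it from a singleton into each
community is computed; communities are ranked by ΔQ.

**Evaluation.** Normalized mutual information (I(A;B) divided by the mean
of the entropies) scores partitions against curated category maps;
redundancy profiles (per-pathway maximum overlap fraction), per-community
gene over-representation (hypergeometric + Benjamini–Hochberg), and a
founder/assignment agreement statistic are included.

## Worked example

The package ships a planted-community generator, so the full pipeline
runs without downloads:

```r
library(pathcomm)
dataset <- generate_collection(synthetic_spec())   # K = 5 planted communities
graph   <- build_graph(dataset$collection)
#> pathway_graph: 100 nodes, 209 edges, total weight 778.2
#> universe 3000 genes, 4950 tested pairs, alpha 0.01 on corrected p

part <- louvain(graph, resolution = 0.4, seed = 1)
#> partition: 100 nodes in 5 communities (sizes 20, 20, 20, 20, 20), gamma = 0.4
modularity_score(graph, part)
#> [1] 0.9192095
evaluate_against_categories(part, dataset$categories)$nmi
#> [1] 1

labels <- label_all_communities(dataset$collection, graph, part)
labels[["0"]][1, ]
#>                          tokens n count mean_hubness
#> 1 antigen presentation response 3    20     15.37263

res <- query_gene_set(dataset$collection$genes[[1]], graph,
                      dataset$collection, part)
head(res$community_ranking, 2)
#>   community      delta_q
#> 1         3  0.119266850
#> 2         0 -0.008935726
```

The detected partition matches the planted truth exactly (NMI = 1), every
community's top label is its planted 3-token name core, and querying a
pathway's own gene set ranks its community first with a clearly positive
modularity gain while all other communities score negative.

A command-line front end (`inst/cli/pathcomm.R`) exposes the same
pipeline as `build`, `detect`, `query`, `evaluate` and `simulate`
subcommands, each writing a manifest (parameters, seeds, input hashes)
sufficient to reproduce the run.

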