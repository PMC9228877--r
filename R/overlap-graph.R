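#' One-sided overlap significance of two gene sets
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap: with `k = |A intersect B|`, `P(X >= k)` for
#' `X ~ Hypergeom(N = universe_size, K = |A|, n = |B|)`. This is the
#' one-sided (enrichment) Fisher's exact test; depletion is meaningless for
#' similarity edges, so the lower tail is never used.
#'
#' @param set_a,set_b character vectors of gene symbols (case-insensitive).
#' @param universe_size size of the gene background; must be at least the
#'   size of either set.
#' @param log10p if `TRUE`, return log10 of the p-value (computed in log
#'   space, so deep tails do not underflow to zero).
#' @return p-value in (0, 1], or its log10.
#' @export
overlap_pvalue <- function(set_a, set_b, universe_size, log10p = FALSE) {
  set_a <- unique(toupper(set_a))
  set_b <- unique(toupper(set_b))
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop("gene sets must be non-empty")
  if (length(set_a) > universe_size || length(set_b) > universe_size)
    stop("gene set larger than the universe")
  k <- length(intersect(set_a, set_b))
  # canonical argument order makes the result exactly symmetric in A and B
  sa <- min(length(set_a), length(set_b))
  sb <- max(length(set_a), length(set_b))
  lp <- stats::phyper(k - 1L, sa, universe_size - sa, sb,
                      lower.tail = FALSE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

#' Build the weighted pathway-similarity graph
#'
#' Tests every unordered pair of pathways for gene overlap with the
#' one-sided hypergeometric test over the collection's universe, Bonferroni-
#' corrects the p-values over all `n(n-1)/2` pairs, and connects pairs whose
#' corrected p-value passes `alpha` with an edge of weight
#' `-log10(p_corrected)` (capped at `weight_cap` so underflowed p-values do
#' not produce infinite weights). Non-significant pairs carry weight zero
#' and are omitted from storage; isolated pathways remain as nodes.
#'
#' @param collection a [geneset_collection()] with at least two pathways.
#' @param alpha significance threshold on the (by default corrected)
#'   p-value; default 0.01.
#' @param weight_cap maximum edge weight; default 300.
#' @param threshold_on `"corrected"` (default) thresholds and weighs the
#'   Bonferroni-corrected p-value; `"raw"` uses the uncorrected p-value for
#'   both, for sensitivity analyses.
#' @return an object of class `pathway_graph`: list with `nodes` (pathway
#'   ids), `edges` (data frame `from`, `to`, `weight`, indices into
#'   `nodes`, `from < to`), `total_weight` (m, each unordered pair counted
#'   once) and `meta` (universe size, tested pairs, alpha, weight cap,
#'   threshold rule).
#' @export
build_graph <- function(collection, alpha = 0.01, weight_cap = 300,
                        threshold_on = c("corrected", "raw")) {
  stopifnot(inherits(collection, "geneset_collection"))
  threshold_on <- match.arg(threshold_on)
  n <- length(collection$ids)
  if (n < 2L) stop("need at least 2 pathways to build a graph")
  stopifnot(alpha > 0, weight_cap > 0)
  N <- length(collection$universe)

  inc <- incidence_matrix(collection)      # genes x pathways, 0/1 sparse
  ov <- as.matrix(Matrix::crossprod(inc))  # pairwise overlap counts
  sizes <- Matrix::colSums(inc)

  pair <- which(upper.tri(ov) & ov > 0, arr.ind = TRUE)
  n_pairs <- n * (n - 1) / 2
  if (nrow(pair) > 0L) {
    k <- ov[pair]
    ka <- pmin(sizes[pair[, 1L]], sizes[pair[, 2L]])  # canonical order,
    kb <- pmax(sizes[pair[, 1L]], sizes[pair[, 2L]])  # as overlap_pvalue
    log10p <- stats::phyper(k - 1, ka, N - ka, kb,
                            lower.tail = FALSE, log.p = TRUE) / log(10)
    if (threshold_on == "corrected")
      log10p <- pmin(0, log10p + log10(n_pairs))
    keep <- log10p <= log10(alpha)
    edges <- data.frame(
      from = pair[keep, 1L], to = pair[keep, 2L],
      weight = pmin(weight_cap, -log10p[keep])
    )
  } else {
    edges <- data.frame(from = integer(0), to = integer(0),
                        weight = numeric(0))
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(nodes = collection$ids, edges = edges,
         total_weight = sum(edges$weight),
         meta = list(universe_size = N, n_pairs = n_pairs, alpha = alpha,
                     weight_cap = weight_cap, threshold_on = threshold_on)),
    class = "pathway_graph"
  )
}

# sparse gene x pathway 0/1 incidence matrix over the universe
incidence_matrix <- function(collection) {
  genes <- collection$universe
  j <- rep.int(seq_along(collection$genes), lengths(collection$genes))
  i <- match(unlist(collection$genes, use.names = FALSE), genes)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(genes), length(collection$ids)),
                       dimnames = list(genes, collection$ids))
}

#' Construct a pathway graph from an explicit edge list
#'
#' Mainly for tests and for importing externally built networks. Edges are
#' given by node id pairs with non-negative weights; zero-weight edges are
#' dropped, self-edges are an error.
#'
#' @param nodes character vector of node ids.
#' @param from,to character vectors of node ids (paired).
#' @param weight numeric vector of non-negative edge weights.
#' @param meta optional list stored as graph metadata.
#' @return a `pathway_graph`.
#' @export
pathway_graph <- function(nodes, from = character(0), to = character(0),
                          weight = numeric(0), meta = list()) {
  stopifnot(!anyDuplicated(nodes),
            length(from) == length(to), length(from) == length(weight),
            all(weight >= 0))
  i <- match(from, nodes)
  j <- match(to, nodes)
  if (anyNA(i) || anyNA(j)) stop("edge endpoint not in node set")
  if (any(i == j)) stop("self-edges are not allowed")
  lo <- pmin(i, j); hi <- pmax(i, j)
  keep <- weight > 0
  edges <- data.frame(from = lo[keep], to = hi[keep], weight = weight[keep])
  if (anyDuplicated(edges[c("from", "to")]))
    stop("duplicate edges")
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 total_weight = sum(edges$weight), meta = meta),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph: %d nodes, %d edges, total weight %.4g\n",
              length(x$nodes), nrow(x$edges), x$total_weight))
  if (!is.null(x$meta$universe_size))
    cat(sprintf("universe %d genes, %g tested pairs, alpha %g on %s p\n",
                x$meta$universe_size, x$meta$n_pairs, x$meta$alpha,
                x$meta$threshold_on))
  invisible(x)
}

# adjacency as parallel lists: nbr[[i]] integer neighbours, wts[[i]] weights
graph_adjacency <- function(graph) {
  n <- length(graph$nodes)
  e <- graph$edges
  nbr <- vector("list", n)
  wts <- vector("list", n)
  src <- c(e$from, e$to)
  dst <- c(e$to, e$from)
  w <- c(e$weight, e$weight)
  ord <- order(src, dst)
  src <- src[ord]; dst <- dst[ord]; w <- w[ord]
  idx <- split(seq_along(src), factor(src, levels = seq_len(n)))
  for (i in seq_len(n)) {
    nbr[[i]] <- dst[idx[[i]]]
    wts[[i]] <- w[idx[[i]]]
  }
  list(nbr = nbr, wts = wts)
}

# weighted degree per node
graph_degrees <- function(graph) {
  n <- length(graph$nodes)
  k <- numeric(n)
  e <- graph$edges
  if (nrow(e) > 0L) {
    agg <- rowsum(c(e$weight, e$weight), c(e$from, e$to))
    k[as.integer(rownames(agg))] <- agg[, 1L]
  }
  k
}

#' Export graph edges as TSV
#'
#' Three columns (`id_a`, `id_b`, `weight`); weights printed with 15
#' significant digits so re-imports are bit-faithful.
#'
#' @param graph a `pathway_graph`.
#' @param path output path.
#' @param header_comment optional character vector written as `#`-prefixed
#'   leading comment lines.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(graph, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  writeLines("id_a\tid_b\tweight", con)
  if (nrow(graph$edges) > 0L)
    writeLines(sprintf("%s\t%s\t%.15g",
                       graph$nodes[graph$edges$from],
                       graph$nodes[graph$edges$to],
                       graph$edges$weight), con)
  invisible(path)
}

#' Export graph nodes as TSV
#'
#' Columns: id, source tag, gene-set size (when a collection is supplied).
#'
#' @param graph a `pathway_graph`.
#' @param path output path.
#' @param collection optional matching [geneset_collection()] providing
#'   source tags and set sizes.
#' @return `path`, invisibly.
#' @export
write_node_tsv <- function(graph, path, collection = NULL) {
  src <- rep("unknown", length(graph$nodes))
  size <- rep(NA_integer_, length(graph$nodes))
  if (!is.null(collection)) {
    m <- match(graph$nodes, collection$ids)
    src <- ifelse(is.na(m), "unknown", collection$sources[m])
    size <- ifelse(is.na(m), NA_integer_, lengths(collection$genes)[m])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("id\tsource\tsize", con)
  writeLines(sprintf("%s\t%s\t%s", graph$nodes, src,
                     ifelse(is.na(size), "NA", size)), con)
  invisible(path)
}

#' Export a weighted graph as GraphML
#'
#' Minimal GraphML with a `weight` edge attribute (double) and, when a
#' partition is supplied, a `community` node attribute. Weights are printed
#' with 15 significant digits.
#'
#' @param graph a `pathway_graph`.
#' @param path output path.
#' @param partition optional [partition()] adding a `community` attribute.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path, partition = NULL) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
    '  <key id="c" for="node" attr.name="community" attr.type="int"/>',
    '  <graph id="G" edgedefault="undirected">'), con)
  comm <- if (!is.null(partition))
    partition$assignment[graph$nodes] else NULL
  for (i in seq_along(graph$nodes)) {
    id <- esc(graph$nodes[i])
    if (!is.null(comm) && !is.na(comm[i]))
      writeLines(sprintf('    <node id="%s"><data key="c">%d</data></node>',
                         id, comm[i]), con)
    else
      writeLines(sprintf('    <node id="%s"/>', id), con)
  }
  if (nrow(graph$edges) > 0L)
    writeLines(sprintf(
      '    <edge source="%s" target="%s"><data key="w">%.15g</data></edge>',
      esc(graph$nodes[graph$edges$from]),
      esc(graph$nodes[graph$edges$to]),
      graph$edges$weight), con)
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(path)
}
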