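# Independent oracles and fixture builders used across the suite.

# upper-tail hypergeometric P(X >= k) by explicit binomial-coefficient
# summation over the pmf (no distribution functions involved)
hyper_tail_oracle <- function(k, size_a, size_b, N) {
  xs <- seq.int(max(k, max(0, size_a + size_b - N)), min(size_a, size_b))
  if (length(xs) == 0L || k > min(size_a, size_b)) return(0)
  sum(choose(size_a, xs) * choose(N - size_a, size_b - xs)) /
    choose(N, size_b)
}

# dense symmetric adjacency matrix of a pathway_graph (diag 0)
adjacency_dense <- function(graph) {
  n <- length(graph$nodes)
  A <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  e <- graph$edges
  A[cbind(e$from, e$to)] <- e$weight
  A[cbind(e$to, e$from)] <- e$weight
  A
}

# modularity from the dense adjacency, written independently of the
# package's edge-list implementation
modularity_oracle <- function(graph, membership, gamma) {
  A <- adjacency_dense(graph)
  m <- sum(A) / 2
  same <- outer(membership, membership, `==`)
  k <- rowSums(A)
  sum(A[same]) / (2 * m) -
    gamma * sum(tapply(k, membership, sum)^2) / (2 * m)^2
}

# all set partitions of n items as restricted-growth strings (rows)
rg_partitions <- function(n) {
  rows <- list(c(1L))
  for (i in seq_len(n - 1L)) {
    rows <- unlist(lapply(rows, function(r) {
      lapply(seq_len(max(r) + 1L), function(g) c(r, g))
    }), recursive = FALSE)
  }
  do.call(rbind, rows)
}

# exhaustive maximum modularity over every partition of the graph's nodes
exhaustive_best_q <- function(graph, gamma) {
  n <- length(graph$nodes)
  A <- adjacency_dense(graph)
  m <- sum(A) / 2
  k <- rowSums(A)
  P <- rg_partitions(n)
  intra <- numeric(nrow(P))
  ksum <- rep(sum(k^2), nrow(P))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same <- P[, i] == P[, j]
      if (A[i, j] > 0) intra <- intra + same * A[i, j]
      ksum <- ksum + same * (2 * k[i] * k[j])
    }
  }
  q <- intra / m - gamma * ksum / (2 * m)^2
  list(q = max(q), membership = P[which.max(q), ])
}

# contingency-table NMI written from first principles
nmi_oracle <- function(a, b) {
  ua <- unique(a); ub <- unique(b)
  n <- length(a)
  tab <- matrix(0, length(ua), length(ub))
  for (i in seq_along(ua))
    for (j in seq_along(ub))
      tab[i, j] <- sum(a == ua[i] & b == ub[j])
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  ent <- function(x) -sum(x[x > 0] * log(x[x > 0]))
  ha <- ent(pa); hb <- ent(pb)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi <- 0
  for (i in seq_along(ua))
    for (j in seq_along(ub))
      if (p[i, j] > 0)
        mi <- mi + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
  mi / ((ha + hb) / 2)
}

# random weighted graph on n nodes; guarantees at least one edge
random_graph <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    on <- stats::runif(nrow(pairs)) < p
    if (!any(on)) next
    w <- round(stats::runif(sum(on), 0.1, 5), 3)
    nodes <- sprintf("n%02d", seq_len(n))
    return(pathway_graph(nodes, nodes[pairs[on, 1L]], nodes[pairs[on, 2L]],
                         w))
  }
}

# small random gene-set collection with enough shared genes to create
# significant overlap edges
random_collection <- function(n_path = 8, seed = 1) {
  set.seed(seed)
  universe <- sprintf("G%03d", 1:300)
  pool_a <- universe[1:60]
  pool_b <- universe[61:120]
  sets <- lapply(seq_len(n_path), function(i) {
    pool <- if (i %% 2 == 0) pool_a else pool_b
    unique(c(sample(pool, 25), sample(universe, 5)))
  })
  names(sets) <- sprintf("PW%02d", seq_len(n_path))
  geneset_collection(sets, universe = universe)
}

# augmented-graph oracle: rebuild the graph with the query as a real node
# (edges computed through the public primitives) and take modularity
# differences with the modularity operation itself
augmented_delta_q <- function(genes, graph, collection, part) {
  N <- graph$meta$universe_size
  n_path <- length(graph$nodes)
  used <- intersect(toupper(genes), collection$universe)
  w_q <- vapply(graph$nodes, function(id) {
    p <- overlap_pvalue(used, collection$genes[[id]], N)
    p_corr <- min(1, p * n_path)
    p_eff <- if (graph$meta$threshold_on == "corrected") p_corr else p
    if (p_eff <= graph$meta$alpha)
      min(graph$meta$weight_cap, -log10(p_corr)) else 0
  }, numeric(1))
  keep <- w_q > 0
  aug <- pathway_graph(c(graph$nodes, "QUERY"),
                       from = c(graph$nodes[graph$edges$from],
                                graph$nodes[keep]),
                       to = c(graph$nodes[graph$edges$to],
                              rep("QUERY", sum(keep))),
                       weight = c(graph$edges$weight, w_q[keep]))
  base <- part$assignment[graph$nodes]
  cid <- sort(unique(part$assignment))
  singleton <- partition(stats::setNames(c(base, max(cid) + 1L),
                                         c(graph$nodes, "QUERY")),
                         resolution = part$resolution)
  q0 <- modularity_score(aug, singleton, resolution = part$resolution)
  vapply(cid, function(c_) {
    moved <- partition(stats::setNames(c(base, c_),
                                       c(graph$nodes, "QUERY")),
                       resolution = part$resolution)
    modularity_score(aug, moved, resolution = part$resolution) - q0
  }, numeric(1))
}

# toy collection with two planted blocks used by several modules
toy_two_block_collection <- function() {
  u <- sprintf("G%03d", 1:120)
  sets <- list(
    KEGG_A1 = u[1:30], KEGG_A2 = u[5:34], REACTOME_A3 = u[1:28],
    KEGG_B1 = u[61:90], REACTOME_B2 = u[65:94], REACTOME_B3 = u[61:88]
  )
  geneset_collection(sets, universe = u)
}
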