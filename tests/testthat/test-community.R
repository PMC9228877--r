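two_triangles <- function() {
  nodes <- letters[1:6]
  pathway_graph(nodes,
                from = c("a", "b", "c", "d", "e", "f"),
                to   = c("b", "c", "a", "e", "f", "d"),
                weight = rep(1, 6))
}

test_that("modularity reproduces closed-form worked examples", {
  g <- two_triangles()
  all_in_one <- partition(setNames(rep(0, 6), g$nodes), resolution = 1)
  expect_equal(modularity_score(g, all_in_one, resolution = 1), 0)
  triangles <- partition(setNames(c(0, 0, 0, 1, 1, 1), g$nodes),
                         resolution = 1)
  expect_equal(modularity_score(g, triangles, resolution = 1), 0.5)
  singletons <- partition(setNames(0:5, g$nodes), resolution = 1)
  expect_equal(modularity_score(g, singletons, resolution = 1), -1 / 6)
})

test_that("modularity agrees with a dense-matrix oracle on random graphs", {
  for (s in 1:10) {
    g <- random_graph(7, p = 0.5, seed = s)
    set.seed(s)
    memb <- sample(0:2, 7, replace = TRUE)
    p <- partition(setNames(memb, g$nodes), resolution = 0.7)
    expect_equal(modularity_score(g, p),
                 modularity_oracle(g, p$assignment[g$nodes], 0.7),
                 tolerance = 1e-12)
  }
})

test_that("modularity is invariant under community relabelling and errors on m=0", {
  g <- random_graph(6, seed = 4)
  memb <- c(0, 1, 0, 2, 1, 2)
  p1 <- partition(setNames(memb, g$nodes), resolution = 1)
  p2 <- partition(setNames(c("x", "y", "z")[memb + 1], g$nodes),
                  resolution = 1)
  expect_equal(modularity_score(g, p1), modularity_score(g, p2))
  empty <- pathway_graph(letters[1:3])
  expect_error(modularity_score(empty, partition(setNames(0:2, letters[1:3]))),
               "edgeless")
})

test_that("louvain separates two cliques joined by a weak bridge", {
  nodes <- sprintf("n%d", 1:8)
  cl <- function(idx) t(combn(idx, 2))
  pairs <- rbind(cl(1:4), cl(5:8), c(4, 5))
  w <- c(rep(1, 12), 1)
  g <- pathway_graph(nodes, nodes[pairs[, 1]], nodes[pairs[, 2]], w)
  p <- louvain(g, resolution = 1, seed = 1)
  expect_equal(n_communities(p), 2L)
  expect_equal(length(unique(p$assignment[nodes[1:4]])), 1L)
  expect_equal(length(unique(p$assignment[nodes[5:8]])), 1L)
  # matches the exhaustive optimum over all 4140 partitions
  best <- exhaustive_best_q(g, 1)
  expect_equal(modularity_score(g, p), best$q, tolerance = 1e-12)
})

test_that("louvain output dominates trivial partitions and is deterministic", {
  for (s in 1:5) {
    g <- random_graph(12, p = 0.4, seed = 100 + s)
    p <- louvain(g, resolution = 0.8, seed = s)
    q <- modularity_score(g, p)
    singles <- partition(setNames(seq_along(g$nodes) - 1, g$nodes),
                         resolution = 0.8)
    ones <- partition(setNames(rep(0, length(g$nodes)), g$nodes),
                      resolution = 0.8)
    expect_gte(q, modularity_score(g, singles) - 1e-12)
    expect_gte(q, modularity_score(g, ones) - 1e-12)
    p2 <- louvain(g, resolution = 0.8, seed = s)
    expect_identical(p$assignment, p2$assignment)
  }
})

test_that("isolated nodes become singleton communities", {
  nodes <- c("a", "b", "c", "iso")
  g <- pathway_graph(nodes, c("a", "b", "c"), c("b", "c", "a"), rep(1, 3))
  p <- louvain(g, resolution = 1, seed = 1)
  expect_equal(length(p$assignment), 4L)
  expect_equal(sum(p$assignment == p$assignment[["iso"]]), 1L)
})

test_that("restarts return the best-modularity partition and record the seed", {
  g <- random_graph(15, p = 0.3, seed = 42)
  p1 <- louvain(g, resolution = 1, seed = 3, restarts = 5)
  qs <- vapply(3:7, function(s)
    modularity_score(g, louvain(g, resolution = 1, seed = s)), numeric(1))
  expect_equal(modularity_score(g, p1), max(qs), tolerance = 1e-12)
  expect_equal(p1$seed, 3L)
})

test_that("partition ids are canonical: 0 is the largest community", {
  p <- partition(c(x1 = "b", x2 = "b", x3 = "b", y1 = "a", y2 = "a",
                   z1 = "c"))
  sizes <- table(p$assignment)
  expect_equal(as.integer(names(sizes)), 0:2)
  expect_true(all(diff(as.integer(sizes)) <= 0))
  expect_equal(unname(p$assignment[c("x1", "y1", "z1")]), c(0L, 1L, 2L))
})

test_that("community aggregation averages pairwise weights and conserves m", {
  nodes <- sprintf("n%d", 1:5)
  g <- pathway_graph(nodes, c("n1", "n3"), c("n3", "n4"), c(4, 2))
  p <- partition(setNames(c(0, 0, 1, 1, 1), nodes), resolution = 1)
  # canonical relabelling: the size-3 block {n3,n4,n5} becomes community 0
  expect_equal(unname(p$assignment[c("n1", "n3")]), c(1L, 0L))
  cg <- aggregate_communities(g, p)
  cross <- cg$edges[cg$edges$comm_a == 0 & cg$edges$comm_b == 1, ]
  expect_equal(cross$avg_weight, 4 / 6)   # one cross edge over 2*3 pairs
  within0 <- cg$edges[cg$edges$comm_a == 0 & cg$edges$comm_b == 0, ]
  expect_equal(within0$avg_weight, 2 / 3) # one intra edge over 3 pairs
  # re-multiplying by pair counts recovers the total weight
  sizes <- setNames(cg$nodes$size, cg$nodes$community)
  tot <- sum(apply(cg$edges, 1, function(r) {
    a <- as.character(r[["comm_a"]]); b <- as.character(r[["comm_b"]])
    pairs <- if (a == b) sizes[a] * (sizes[a] - 1) / 2
             else sizes[a] * sizes[b]
    r[["avg_weight"]] * pairs
  }))
  expect_equal(tot, g$total_weight, tolerance = 1e-9)
})

test_that("aggregation conserves total weight on random graphs", {
  for (s in 1:5) {
    g <- random_graph(10, p = 0.5, seed = 200 + s)
    p <- louvain(g, resolution = 0.6, seed = s)
    cg <- aggregate_communities(g, p)
    sizes <- setNames(cg$nodes$size, cg$nodes$community)
    tot <- sum(vapply(seq_len(nrow(cg$edges)), function(i) {
      a <- as.character(cg$edges$comm_a[i])
      b <- as.character(cg$edges$comm_b[i])
      pairs <- if (a == b) sizes[a] * (sizes[a] - 1) / 2
               else sizes[a] * sizes[b]
      cg$edges$avg_weight[i] * pairs
    }, numeric(1)))
    expect_equal(tot, g$total_weight, tolerance = 1e-9)
  }
})

test_that("hubness is the intra-community weighted degree", {
  nodes <- c("a", "b", "c", "hub", "l1", "l2", "l3")
  g <- pathway_graph(
    nodes,
    from = c("a", "b", "c", "hub", "hub", "hub", "a"),
    to   = c("b", "c", "a", "l1", "l2", "l3", "hub"),
    weight = c(2, 2, 2, 1, 1, 1, 5))
  p <- partition(setNames(c(0, 0, 0, 1, 1, 1, 1), nodes), resolution = 1)
  h <- hubness(g, p)
  expect_equal(unname(h[c("a", "b", "c")]), c(4, 4, 4))  # triangle, w = 2
  expect_equal(unname(h[["hub"]]), 3)   # star centre; cross edge excluded
  expect_equal(unname(h[["l1"]]), 1)
  expect_error(hubness(g, p, nodes = "missing"), "unknown node")
})

test_that("partition TSV round-trips with resolution and seed metadata", {
  g <- random_graph(9, seed = 31)
  p <- louvain(g, resolution = 0.4, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_partition_tsv(p, path)
  back <- read_partition_tsv(path)
  expect_identical(back$assignment, p$assignment)
  expect_equal(back$resolution, 0.4)
  expect_equal(back$seed, 9L)
})

test_that("louvain communities agree with an independent implementation", {
  skip_if_not_installed("igraph")
  d <- generate_collection(synthetic_spec(seed = 13))
  g <- build_graph(d$collection)
  p <- louvain(g, resolution = 1, seed = 2)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g$nodes[g$edges$from], to = g$nodes[g$edges$to],
               weight = g$edges$weight),
    directed = FALSE, vertices = g$nodes)
  ip <- igraph::cluster_louvain(ig, resolution = 1)
  ours <- p$assignment[igraph::V(ig)$name]
  theirs <- igraph::membership(ip)
  expect_gte(nmi(setNames(ours, names(ours)),
                 setNames(as.integer(theirs), names(ours))), 0.95)
})
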