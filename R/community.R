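#' Construct a partition of graph nodes into communities
#'
#' Community ids are canonicalized to `0..C-1` with community 0 the largest
#' (ties broken by the lexicographically smallest member id), so partitions
#' from different runs are directly comparable.
#'
#' @param assignment named vector: node id -> community label (any atomic
#'   labels; they are relabelled).
#' @param resolution the resolution parameter gamma used to produce the
#'   partition (1 for externally supplied groupings unless known).
#' @param seed integer seed that produced the partition, or `NA`.
#' @return object of class `partition`: list with `assignment` (named
#'   integer vector, 0-based), `resolution`, `seed`.
#' @export
partition <- function(assignment, resolution = 1, seed = NA_integer_) {
  ids <- names(assignment)
  if (is.null(ids) || anyDuplicated(ids))
    stop("assignment must be named by unique node ids")
  stopifnot(resolution > 0)
  relab <- canonical_labels(assignment)
  structure(list(assignment = relab, resolution = resolution,
                 seed = as.integer(seed)),
            class = "partition")
}

# relabel communities 0..C-1: by decreasing size, ties by smallest member id
canonical_labels <- function(assignment) {
  f <- as.factor(assignment)
  sizes <- tabulate(f)
  min_member <- vapply(split(names(assignment), f), min, character(1))
  ord <- order(-sizes, min_member)
  new_id <- integer(nlevels(f))
  new_id[ord] <- seq_len(nlevels(f)) - 1L
  stats::setNames(new_id[as.integer(f)], names(assignment))
}

#' @export
print.partition <- function(x, ...) {
  sizes <- table(x$assignment)
  cat(sprintf(
    "partition: %d nodes in %d communities (sizes %s), gamma = %g\n",
    length(x$assignment), length(sizes),
    paste(utils::head(as.integer(sizes), 10), collapse = ", "),
    x$resolution))
  invisible(x)
}

#' Number of communities in a partition
#' @param x a [partition()].
#' @return integer count.
#' @export
n_communities <- function(x) length(unique(x$assignment))

#' Weighted modularity of a partition
#'
#' Computes `Q = sum_c [ S_in(c)/(2m) - gamma * (S_tot(c)/(2m))^2 ]`, where
#' `S_in(c)` is twice the total weight of intra-community edges, `S_tot(c)`
#' the sum of weighted degrees of members, and `m` the graph's total edge
#' weight. The resolution `gamma` scales only the degree-null term: larger
#' values favour more, smaller communities.
#'
#' @param graph a `pathway_graph` with positive total weight.
#' @param partition a [partition()] covering every graph node.
#' @param resolution gamma > 0; defaults to the partition's own.
#' @return the modularity Q.
#' @export
modularity_score <- function(graph, partition,
                             resolution = partition$resolution) {
  stopifnot(inherits(graph, "pathway_graph"), inherits(partition, "partition"),
            resolution > 0)
  m <- graph$total_weight
  if (m <= 0) stop("modularity undefined on edgeless graph")
  comm <- partition$assignment[graph$nodes]
  if (anyNA(comm)) stop("partition does not cover all graph nodes")
  e <- graph$edges
  intra <- sum(e$weight[comm[e$from] == comm[e$to]])
  k <- graph_degrees(graph)
  sigma_tot <- rowsum(k, comm)[, 1L]
  2 * intra / (2 * m) - resolution * sum((sigma_tot / (2 * m))^2)
}

# evaluate and restore RNG state around a seeded computation
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Louvain community detection with a resolution parameter
#'
#' Native two-phase Louvain: repeated single-node moves to the neighbouring
#' community with the largest positive modularity gain (node order shuffled
#' from the seed each pass; ties keep the current community, and among new
#' communities the lowest id wins), followed by graph aggregation with
#' self-loops, iterated until no move improves Q by more than `1e-12`.
#' With `restarts > 1` the algorithm reruns with consecutive seeds
#' `seed..seed+restarts-1` and returns the partition of highest modularity.
#' Isolated nodes end up as singleton communities.
#'
#' @param graph a `pathway_graph` with positive total weight.
#' @param resolution gamma > 0; default 0.4, which favours coarse
#'   communities on dense overlap networks.
#' @param seed integer controlling node visit order; identical inputs give
#'   identical partitions.
#' @param restarts number of independent seeded runs; best Q wins.
#' @return a [partition()].
#' @export
louvain <- function(graph, resolution = 0.4, seed = 1L, restarts = 1L) {
  stopifnot(inherits(graph, "pathway_graph"), resolution > 0, restarts >= 1)
  if (graph$total_weight <= 0)
    stop("community detection undefined on edgeless graph")
  best <- NULL
  best_q <- -Inf
  for (s in seq.int(seed, seed + restarts - 1L)) {
    memb <- with_seed(s, louvain_run(graph, resolution))
    p <- partition(stats::setNames(memb, graph$nodes),
                   resolution = resolution, seed = s)
    q <- modularity_score(graph, p)
    if (q > best_q + 1e-12) {
      best <- p
      best_q <- q
    }
  }
  best$seed <- as.integer(seed)
  best
}

# single seeded Louvain run; returns integer membership for graph$nodes
louvain_run <- function(graph, resolution) {
  n <- length(graph$nodes)
  e <- graph$edges
  # working multigraph: edge list with from <= to; a from == to row holds
  # the "both directions" internal weight A_cc of an aggregated node
  ef <- e$from; et <- e$to; ew <- e$weight
  m <- graph$total_weight
  memb_full <- seq_len(n)          # original node -> current top-level comm
  repeat {
    lvl <- louvain_level(ef, et, ew, m, resolution,
                         n_nodes = max(memb_full))
    if (!lvl$improved) break
    memb_full <- lvl$comm[memb_full]
    # aggregate: communities become nodes
    agg <- aggregate_edges(lvl$comm, ef, et, ew)
    ef <- agg$from; et <- agg$to; ew <- agg$weight
    memb_full <- match(memb_full, sort(unique(memb_full)))
    if (length(unique(memb_full)) == 1L) break
  }
  memb_full
}

# one local-move phase on a multigraph given as an edge list
# (self rows from==to carry both-direction internal weight)
louvain_level <- function(ef, et, ew, m, resolution, n_nodes) {
  n <- n_nodes
  self_w <- numeric(n)
  sl <- ef == et
  if (any(sl)) {
    agg <- rowsum(ew[sl], ef[sl])
    self_w[as.integer(rownames(agg))] <- agg[, 1L]
  }
  f <- ef[!sl]; t <- et[!sl]; w <- ew[!sl]
  nbr <- vector("list", n); wts <- vector("list", n)
  src <- c(f, t); dst <- c(t, f); ww <- c(w, w)
  sp <- split(seq_along(src), factor(src, levels = seq_len(n)))
  for (i in seq_len(n)) {
    nbr[[i]] <- dst[sp[[i]]]
    wts[[i]] <- ww[sp[[i]]]
  }
  k <- self_w + vapply(wts, sum, numeric(1))
  comm <- seq_len(n)
  sigma_tot <- k
  two_m <- 2 * m
  improved_any <- FALSE
  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      if (length(nbr[[i]]) == 0L) next
      ci <- comm[i]
      nc <- comm[nbr[[i]]]
      w_to <- rowsum(wts[[i]], nc)
      cand <- as.integer(rownames(w_to))
      w_to <- w_to[, 1L]
      sigma_tot[ci] <- sigma_tot[ci] - k[i]
      gain <- w_to / m - 2 * resolution * sigma_tot[cand] * k[i] / (two_m^2)
      stay <- match(ci, cand)
      gain_stay <- if (is.na(stay))
        -2 * resolution * sigma_tot[ci] * k[i] / (two_m^2) else gain[stay]
      best <- which(gain == max(gain))
      target <- cand[best[which.min(cand[best])]]
      if (max(gain) > gain_stay + 1e-12 && target != ci) {
        comm[i] <- target
        sigma_tot[target] <- sigma_tot[target] + k[i]
        improved <- TRUE
        improved_any <- TRUE
      } else {
        sigma_tot[ci] <- sigma_tot[ci] + k[i]
      }
    }
    if (!improved) break
  }
  list(comm = match(comm, sort(unique(comm))), improved = improved_any)
}

# collapse an edge list by community membership; returns from <= to rows,
# with from == to rows holding the both-direction internal weight
aggregate_edges <- function(comm, ef, et, ew) {
  cf <- comm[ef]; ct <- comm[et]
  lo <- pmin(cf, ct); hi <- pmax(cf, ct)
  sl <- ef == et                       # existing self rows keep their value
  w <- ifelse(lo == hi & !sl, 2 * ew, ew)
  key <- paste(lo, hi)
  agg <- rowsum(w, key)
  parts <- strsplit(rownames(agg), " ", fixed = TRUE)
  list(from = vapply(parts, function(p) as.integer(p[1]), integer(1)),
       to = vapply(parts, function(p) as.integer(p[2]), integer(1)),
       weight = agg[, 1L])
}

#' Aggregate a pathway graph at the community level
#'
#' Collapses communities to single nodes; the value attached to a community
#' pair is the average pairwise weight between member sets, i.e. total
#' cross-weight divided by `|a|*|b|` (absent edges count as zero). Self
#' pairs use the number of unordered member pairs `|c|(|c|-1)/2` as the
#' denominator; singleton communities report 0.
#'
#' @param graph a `pathway_graph`.
#' @param partition a [partition()] covering the graph.
#' @return object of class `community_graph`: `nodes` data frame
#'   (`community`, `size`) and `edges` data frame (`comm_a`, `comm_b`,
#'   `avg_weight`), including a self row per community.
#' @export
aggregate_communities <- function(graph, partition) {
  stopifnot(inherits(graph, "pathway_graph"), inherits(partition, "partition"))
  comm <- partition$assignment[graph$nodes]
  if (anyNA(comm)) stop("partition does not cover all graph nodes")
  cid <- sort(unique(partition$assignment))
  sizes <- as.integer(table(factor(comm, levels = cid)))
  e <- graph$edges
  ca <- pmin(comm[e$from], comm[e$to])
  cb <- pmax(comm[e$from], comm[e$to])
  totals <- if (nrow(e) > 0L)
    rowsum(e$weight, paste(ca, cb)) else matrix(numeric(0))
  self <- data.frame(comm_a = cid, comm_b = cid)
  cross <- if (nrow(e) > 0L) {
    parts <- strsplit(rownames(totals), " ", fixed = TRUE)
    data.frame(comm_a = vapply(parts, function(p) as.integer(p[1]), integer(1)),
               comm_b = vapply(parts, function(p) as.integer(p[2]), integer(1)))
  } else data.frame(comm_a = integer(0), comm_b = integer(0))
  pairs <- unique(rbind(self, cross[cross$comm_a != cross$comm_b, ]))
  key <- paste(pairs$comm_a, pairs$comm_b)
  tot <- rep(0, nrow(pairs))
  hit <- match(key, rownames(totals))
  tot[!is.na(hit)] <- totals[hit[!is.na(hit)], 1L]
  na_ <- match(pairs$comm_a, cid); nb_ <- match(pairs$comm_b, cid)
  denom <- ifelse(pairs$comm_a == pairs$comm_b,
                  sizes[na_] * (sizes[na_] - 1) / 2,
                  sizes[na_] * sizes[nb_])
  avg <- ifelse(denom > 0, tot / denom, 0)
  edges <- data.frame(comm_a = pairs$comm_a, comm_b = pairs$comm_b,
                      avg_weight = avg)
  edges <- edges[order(edges$comm_a, edges$comm_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = data.frame(community = cid, size = sizes),
                 edges = edges),
            class = "community_graph")
}

#' @export
print.community_graph <- function(x, ...) {
  cat(sprintf("community_graph: %d communities, %d edge records\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Intra-community weighted degree (hubness)
#'
#' A pathway's hubness is its weighted degree within the induced subgraph of
#' its own community: the sum of edge weights to same-community neighbours.
#' High-hubness members are the pathways most densely tied into their
#' community.
#'
#' @param graph a `pathway_graph`.
#' @param partition a [partition()] covering the graph.
#' @param nodes node ids to score; defaults to all graph nodes.
#' @return named numeric vector of hubness scores.
#' @export
hubness <- function(graph, partition, nodes = graph$nodes) {
  stopifnot(inherits(graph, "pathway_graph"), inherits(partition, "partition"))
  comm <- partition$assignment[graph$nodes]
  if (anyNA(comm)) stop("partition does not cover all graph nodes")
  idx <- match(nodes, graph$nodes)
  if (anyNA(idx)) stop("unknown node: ", nodes[is.na(idx)][1L])
  e <- graph$edges
  h <- numeric(length(graph$nodes))
  if (nrow(e) > 0L) {
    intra <- comm[e$from] == comm[e$to]
    if (any(intra)) {
      agg <- rowsum(c(e$weight[intra], e$weight[intra]),
                    c(e$from[intra], e$to[intra]))
      h[as.integer(rownames(agg))] <- agg[, 1L]
    }
  }
  stats::setNames(h[idx], nodes)
}

#' Write a partition as TSV
#'
#' Two columns (pathway id, community id), preceded by a comment line
#' recording the resolution and seed for reproducibility.
#'
#' @param partition a [partition()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(partition, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# resolution=%.15g seed=%s", partition$resolution,
                     ifelse(is.na(partition$seed), "NA", partition$seed)),
             con)
  writeLines("id\tcommunity", con)
  writeLines(sprintf("%s\t%d", names(partition$assignment),
                     partition$assignment), con)
  invisible(path)
}

#' Read a partition from TSV
#'
#' Accepts the format written by [write_partition_tsv()] or any two-column
#' TSV of node id and community label (for importing partitions produced by
#' other algorithms).
#'
#' @param path input path.
#' @return a [partition()] (resolution from the header comment if present,
#'   else 1).
#' @export
read_partition_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  resolution <- 1
  seed <- NA_integer_
  hdr <- grep("^#", lines, value = TRUE)
  if (length(hdr) > 0L) {
    rmatch <- regmatches(hdr[1], regexec("resolution=([0-9.eE+-]+)", hdr[1]))[[1]]
    if (length(rmatch) == 2L) resolution <- as.numeric(rmatch[2])
    smatch <- regmatches(hdr[1], regexec("seed=([0-9]+)", hdr[1]))[[1]]
    if (length(smatch) == 2L) seed <- as.integer(smatch[2])
  }
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) > 0L && grepl("^id\t", lines[1])) lines <- lines[-1]
  if (length(lines) == 0L) stop("no assignments in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) stop("malformed partition line")
  partition(stats::setNames(vapply(fields, `[[`, character(1), 2L),
                            vapply(fields, `[[`, character(1), 1L)),
            resolution = resolution, seed = seed)
}
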