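#' Query a novel gene set against a learned community network
#'
#' Scores a new gene set in two coupled ways. First, per-pathway
#' enrichment: a one-sided hypergeometric p-value against every pathway,
#' over the graph's stored universe, Bonferroni-corrected over the number
#' of pathways (the correction family a user running the same enrichment
#' test would face). Second, community ranking: the query is temporarily
#' added to the graph as a new node, with edges weighted exactly as
#' [build_graph()] would weight them (same threshold rule, cap, and the
#' pathway-count correction family for the query's own tests); then,
#' holding the learned partition fixed and starting from the query as a
#' singleton community, the modularity change of moving the query into each
#' existing community is computed at the partition's resolution, with the
#' total weight updated for the temporary edges. Communities are ranked by
#' decreasing modularity gain. The graph and partition are not modified.
#'
#' Query genes absent from the universe are dropped (and counted) rather
#' than enlarging the universe, which would silently change every stored
#' edge's null distribution.
#'
#' @param genes character vector of query gene symbols.
#' @param graph the `pathway_graph` built from `collection`.
#' @param collection the [geneset_collection()] the graph was built from.
#' @param partition a [partition()] of the graph.
#' @return object of class `query_result`: list with
#'   `pathway_enrichment` (data frame `id`, `p_raw`, `p_corrected`, sorted
#'   by corrected p), `community_ranking` (data frame `community`,
#'   `delta_q`, sorted by gain), `best_community` (top community id, or
#'   `NA` when no move increases modularity), `genes_used`, `genes_dropped`.
#' @export
query_gene_set <- function(genes, graph, collection, partition) {
  stopifnot(inherits(graph, "pathway_graph"),
            inherits(collection, "geneset_collection"),
            inherits(partition, "partition"))
  comm <- partition$assignment[graph$nodes]
  if (anyNA(comm)) stop("partition does not cover all graph nodes")
  genes <- unique(toupper(genes))
  genes <- genes[nzchar(genes)]
  in_universe <- genes %in% collection$universe
  used <- genes[in_universe]
  if (length(used) == 0L)
    stop("no query gene is present in the graph's universe")

  N <- graph$meta$universe_size
  n_path <- length(graph$nodes)
  idx <- match(graph$nodes, collection$ids)
  log10p <- vapply(idx, function(i) {
    overlap_pvalue(used, collection$genes[[i]], N, log10p = TRUE)
  }, numeric(1))
  p_raw <- 10^log10p
  log10p_corr <- pmin(0, log10p + log10(n_path))
  enrich <- data.frame(id = graph$nodes, p_raw = p_raw,
                       p_corrected = 10^log10p_corr)
  enrich <- enrich[order(enrich$p_corrected, enrich$p_raw, enrich$id), ,
                   drop = FALSE]
  rownames(enrich) <- NULL

  # temporary node edges, weighted as build_graph would
  log10p_for_edges <- if (graph$meta$threshold_on == "corrected")
    log10p_corr else log10p
  sig <- log10p_for_edges <= log10(graph$meta$alpha)
  w_q <- ifelse(sig, pmin(graph$meta$weight_cap, -log10p_for_edges), 0)

  k_q <- sum(w_q)                        # query node degree
  m_aug <- graph$total_weight + k_q
  cid <- sort(unique(partition$assignment))
  delta_q <- if (m_aug > 0) {
    k_to <- vapply(cid, function(c_) sum(w_q[comm == c_]), numeric(1))
    k <- graph_degrees(graph) + w_q      # degrees in the augmented graph
    sigma_tot <- vapply(cid, function(c_) sum(k[comm == c_]), numeric(1))
    k_to / m_aug - partition$resolution * sigma_tot * k_q / (2 * m_aug^2)
  } else rep(0, length(cid))
  ranking <- data.frame(community = cid, delta_q = delta_q)
  ranking <- ranking[order(-ranking$delta_q, ranking$community), ,
                     drop = FALSE]
  rownames(ranking) <- NULL
  structure(
    list(pathway_enrichment = enrich,
         community_ranking = ranking,
         best_community = if (nrow(ranking) > 0L && ranking$delta_q[1L] > 0)
           ranking$community[1L] else NA_integer_,
         genes_used = length(used),
         genes_dropped = sum(!in_universe)),
    class = "query_result"
  )
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("query_result: %d genes used, %d dropped\n",
              x$genes_used, x$genes_dropped))
  cat("top communities by modularity gain:\n")
  print(utils::head(x$community_ranking, 5))
  cat("top enriched pathways:\n")
  print(utils::head(x$pathway_enrichment, 5))
  invisible(x)
}

#' Write a query report as JSON and TSV
#'
#' JSON carries the top-k enriched pathways, the full community ranking
#' with modularity gains, and the gene accounting; the TSV holds the full
#' enrichment table.
#'
#' @param result a `query_result`.
#' @param json_path output JSON path (`NULL` to skip).
#' @param tsv_path output TSV path (`NULL` to skip).
#' @param top_k pathways included in the JSON report; default 20.
#' @return `result`, invisibly.
#' @export
write_query_report <- function(result, json_path = NULL, tsv_path = NULL,
                               top_k = 20) {
  stopifnot(inherits(result, "query_result"))
  if (!is.null(json_path)) {
    payload <- list(
      genes_used = result$genes_used,
      genes_dropped = result$genes_dropped,
      best_community = if (is.na(result$best_community)) "singleton"
                       else result$best_community,
      top_pathways = utils::head(result$pathway_enrichment, top_k),
      community_ranking = result$community_ranking
    )
    jsonlite::write_json(payload, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    con <- file(tsv_path, "w")
    writeLines("id\tp_raw\tp_corrected", con)
    writeLines(sprintf("%s\t%.15g\t%.15g", result$pathway_enrichment$id,
                       result$pathway_enrichment$p_raw,
                       result$pathway_enrichment$p_corrected), con)
    close(con)
  }
  invisible(result)
}
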