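#' Default stop-word list for pathway-name tokenization
#'
#' A standard English stop-word list shipped with the package. Domain terms
#' that carry meaning in pathway names (e.g. "pathway", "process",
#' "regulation") are deliberately kept, since GO and REACTOME names use
#' them contrastively.
#'
#' @return character vector of lower-case stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords.txt", package = "pathcomm",
                      mustWork = TRUE)
  readLines(path, warn = FALSE)
}

# database identifier tokens dropped from the front of pathway names
DB_IDENTIFIERS <- c("kegg", "reactome", "gobp", "gomf", "go", "hallmark",
                    "biocarta", "wp", "pid")

#' Tokenize a pathway name
#'
#' Splits on underscores and whitespace, lower-cases, drops a leading
#' database-identifier token (kegg, reactome, gobp, gomf, go, hallmark,
#' ...), and removes stop words while preserving token order.
#'
#' @param name pathway name string.
#' @param stopwords lower-case stop words; default [default_stopwords()].
#' @return character vector of tokens (possibly empty).
#' @export
tokenize_name <- function(name, stopwords = default_stopwords()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  tokens <- tolower(strsplit(name, "[_[:space:]]+")[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) > 0L && tokens[1L] %in% DB_IDENTIFIERS)
    tokens <- tokens[-1L]
  tokens[!(tokens %in% stopwords)]
}

# distinct contiguous n-grams of a token vector, as "a b c" strings
ngrams <- function(tokens, n) {
  if (length(tokens) < n) return(character(0))
  unique(vapply(seq_len(length(tokens) - n + 1L), function(i) {
    paste(tokens[i:(i + n - 1L)], collapse = " ")
  }, character(1)))
}

#' Rank descriptive label candidates for one community
#'
#' Counts contiguous token 3-mers across member pathway names (each pathway
#' supports a given n-gram at most once), keeps those appearing in at least
#' `min_count` members, and ranks by count, then by the average hubness of
#' the supporting pathways, then lexicographically. If no 3-mer qualifies
#' the procedure falls back to 2-mers, then 1-mers, and finally to 1-mers
#' with no count floor, so every non-empty community receives a label.
#'
#' @param names character vector of member pathway names.
#' @param hubness_scores numeric vector of hubness values parallel to
#'   `names` (or named by them); defaults to zeros, which disables the
#'   hubness tie-break.
#' @param min_count minimum member support for a candidate; default 3.
#' @param stopwords stop-word list for tokenization.
#' @return data frame with columns `tokens` (space-joined n-gram), `n`
#'   (n-gram order), `count`, `mean_hubness`, ranked best first. The top
#'   row is the community's label.
#' @export
label_community <- function(names, hubness_scores = NULL, min_count = 3,
                            stopwords = default_stopwords()) {
  if (length(names) == 0L) stop("cannot label an empty community")
  if (is.null(hubness_scores)) hubness_scores <- numeric(length(names))
  if (!is.null(base::names(hubness_scores)))
    hubness_scores <- hubness_scores[names]
  stopifnot(length(hubness_scores) == length(names))
  token_lists <- lapply(names, tokenize_name, stopwords = stopwords)

  rank_ngrams <- function(n, floor_) {
    per_path <- lapply(token_lists, ngrams, n = n)
    grams <- unlist(per_path, use.names = FALSE)
    if (length(grams) == 0L) return(NULL)
    path_idx <- rep.int(seq_along(per_path), lengths(per_path))
    counts <- table(grams)
    keep <- names(counts)[counts >= floor_]
    if (length(keep) == 0L) return(NULL)
    mh <- vapply(keep, function(g) {
      mean(hubness_scores[path_idx[grams == g]])
    }, numeric(1))
    out <- data.frame(tokens = keep, n = n,
                      count = as.integer(counts[keep]),
                      mean_hubness = unname(mh))
    out[order(-out$count, -out$mean_hubness, out$tokens), , drop = FALSE]
  }

  for (spec in list(c(3, min_count), c(2, min_count), c(1, min_count),
                    c(1, 1))) {
    ranked <- rank_ngrams(spec[1], spec[2])
    if (!is.null(ranked)) {
      rownames(ranked) <- NULL
      return(ranked)
    }
  }
  # names tokenized to nothing (all stop words / identifiers)
  data.frame(tokens = character(0), n = integer(0), count = integer(0),
             mean_hubness = numeric(0))
}

#' Label every community of a partition
#'
#' Applies [label_community()] per community, using intra-community
#' weighted degree as the hubness tie-break.
#'
#' @param collection a [geneset_collection()] providing display names.
#' @param graph the `pathway_graph` the partition was detected on.
#' @param partition a [partition()].
#' @param top_k number of ranked candidates retained per community.
#' @param ... passed to [label_community()].
#' @return named list: community id (as character) -> candidate data frame.
#' @export
label_all_communities <- function(collection, graph, partition, top_k = 10,
                                  ...) {
  h <- hubness(graph, partition)
  comm <- partition$assignment
  out <- lapply(sort(unique(comm)), function(c_id) {
    members <- names(comm)[comm == c_id]
    disp <- collection$names[match(members, collection$ids)]
    cand <- label_community(disp, hubness_scores = stats::setNames(
      unname(h[members]), disp), ...)
    utils::head(cand, top_k)
  })
  stats::setNames(out, as.character(sort(unique(comm))))
}

#' Write a community label report as JSON
#'
#' One entry per community with its ranked candidates (tokens, n-gram
#' order, member support and mean hubness).
#'
#' @param labels result of [label_all_communities()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_report <- function(labels, path) {
  jsonlite::write_json(labels, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
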