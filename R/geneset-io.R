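#' Construct a gene-set collection
#'
#' A `geneset_collection` is an ordered list of named gene sets together with
#' the gene universe they live in. The universe defaults to the union of all
#' member genes, which is the only background computable from the collection
#' alone; an explicit background (e.g. all assayed genes) can be supplied
#' instead and must contain that union.
#'
#' @param sets named list of character vectors; names are pathway ids, values
#'   are gene symbols. Symbols are upper-cased and deduplicated.
#' @param names optional character vector of display names, same length as
#'   `sets` (defaults to the ids).
#' @param sources optional character vector of database tags; if `NULL`, tags
#'   are inferred from id prefixes (`KEGG`, `REACTOME`, `GOBP`, `GOMF`), else
#'   `"unknown"`.
#' @param universe optional character vector overriding the default universe.
#' @return an object of class `geneset_collection` with components `ids`,
#'   `names`, `sources`, `genes` (list of character vectors) and `universe`.
#' @export
geneset_collection <- function(sets, names = NULL, sources = NULL,
                               universe = NULL) {
  ids <- base::names(sets)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("every gene set must have a non-empty id")
  if (anyDuplicated(ids))
    stop("duplicate pathway id: ", ids[duplicated(ids)][1L])
  genes <- lapply(sets, function(g) {
    g <- unique(toupper(as.character(g)))
    g <- g[!is.na(g) & g != ""]
    g
  })
  empty <- lengths(genes) == 0L
  if (any(empty))
    stop("gene set has no genes: ", ids[empty][1L])
  if (is.null(names)) names <- ids
  stopifnot(length(names) == length(ids))
  if (is.null(sources)) sources <- infer_source(ids)
  stopifnot(length(sources) == length(ids))
  union_genes <- unique(unlist(genes, use.names = FALSE))
  if (is.null(universe)) {
    universe <- sort(union_genes)
  } else {
    universe <- unique(toupper(as.character(universe)))
    missing <- setdiff(union_genes, universe)
    if (length(missing) > 0L)
      stop("universe does not cover all pathway genes (e.g. ",
           missing[1L], ")")
    universe <- sort(universe)
  }
  structure(
    list(ids = ids, names = unname(names), sources = unname(sources),
         genes = genes, universe = universe),
    class = "geneset_collection"
  )
}

infer_source <- function(ids) {
  prefixes <- c(KEGG = "KEGG", REACTOME = "REACTOME",
                GOBP = "GOBP", GOMF = "GOMF")
  vapply(ids, function(id) {
    tok <- toupper(sub("[_ ].*$", "", id))
    if (tok %in% prefixes) unname(prefixes[[tok]]) else "unknown"
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("geneset_collection: %d gene sets, universe of %d genes\n",
              length(x$ids), length(x$universe)))
  srcs <- table(x$sources)
  cat("sources:", paste(sprintf("%s (%d)", names(srcs), srcs),
                        collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.geneset_collection <- function(x) length(x$ids)

#' Read a GMT gene-set file
#'
#' GMT is the tab-separated MSigDB distribution format: one gene set per
#' line, fields are id, description, then one gene symbol per field.
#'
#' @param path path to a GMT file.
#' @param universe optional character vector overriding the default gene
#'   universe (union of all genes read).
#' @return a [geneset_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("no gene sets in ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad))
    stop(sprintf("malformed GMT line %d in %s: fewer than 3 fields",
                 keep[bad][1L], path))
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate pathway id in ", path, ": ", ids[duplicated(ids)][1L])
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- ids
  geneset_collection(sets, universe = universe)
}

#' Write a gene-set collection as GMT
#'
#' The description field is the display name. Genes are written in stored
#' (sorted, upper-case) order so output is deterministic.
#'
#' @param collection a [geneset_collection()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "geneset_collection"))
  lines <- vapply(seq_along(collection$ids), function(i) {
    paste(c(collection$ids[i], collection$names[i],
            sort(collection$genes[[i]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Merge gene-set collections into one
#'
#' Used when a joint network spans several databases: collections are
#' concatenated in input order and a shared universe (union, unless
#' overridden) is derived. Duplicate ids across inputs are an error.
#'
#' @param ... `geneset_collection` objects.
#' @param universe optional explicit universe.
#' @return a single [geneset_collection()].
#' @export
merge_collections <- function(..., universe = NULL) {
  colls <- list(...)
  if (length(colls) == 1L && is.list(colls[[1]]) &&
      !inherits(colls[[1]], "geneset_collection"))
    colls <- colls[[1]]
  stopifnot(all(vapply(colls, inherits, logical(1), "geneset_collection")))
  ids <- unlist(lapply(colls, `[[`, "ids"), use.names = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate pathway id across collections: ",
         ids[duplicated(ids)][1L])
  sets <- do.call(c, lapply(colls, `[[`, "genes"))
  names(sets) <- ids
  geneset_collection(
    sets,
    names = unlist(lapply(colls, `[[`, "names"), use.names = FALSE),
    sources = unlist(lapply(colls, `[[`, "sources"), use.names = FALSE),
    universe = universe
  )
}

#' Read a pathway-to-category map
#'
#' Two-column TSV (pathway id, category label). Curated category labels act
#' as ground truth when scoring detected communities. On duplicate ids the
#' last assignment wins, with a warning.
#'
#' @param path path to a two-column TSV.
#' @return named character vector: pathway id -> category label.
#' @export
read_category_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- character(0)
    names(out) <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 2L
  if (any(bad))
    stop("malformed category map line: ", lines[bad][1L])
  ids <- vapply(fields, `[[`, character(1), 1L)
  labels <- vapply(fields, `[[`, character(1), 2L)
  if (anyDuplicated(ids)) {
    warning("duplicate pathway ids in category map; last assignment wins: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    keep <- !duplicated(ids, fromLast = TRUE)
    ids <- ids[keep]
    labels <- labels[keep]
  }
  stats::setNames(labels, ids)
}

#' Read a query gene list
#'
#' One gene symbol per line; blank lines ignored; symbols upper-cased and
#' deduplicated.
#'
#' @param path path to a text file.
#' @return character vector of unique upper-case gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- toupper(trimws(readLines(path, warn = FALSE)))
  genes <- unique(lines[nzchar(lines)])
  if (length(genes) == 0L) stop("no genes read from ", path)
  genes
}
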