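# community-specific vocabulary for planted pathway names; 3 tokens per
# community form the recoverable label core
CORE_VOCAB <- c(
  "glucose", "catabolic", "flux", "axon", "guidance", "signaling",
  "antigen", "presentation", "response", "lipid", "droplet", "assembly",
  "chromatin", "remodeling", "complex", "ribosome", "biogenesis", "export",
  "calcium", "channel", "transport", "cytokine", "receptor", "cascade",
  "dna", "damage", "checkpoint", "vesicle", "membrane", "fusion",
  "oxidative", "stress", "defense", "amino", "acid", "synthesis",
  "cell", "cycle", "arrest", "protein", "folding", "quality",
  "heme", "iron", "uptake", "actin", "filament", "dynamics"
)

#' Specification for a synthetic planted-community collection
#'
#' Describes a gene-set collection with planted community structure: `K`
#' pairwise-disjoint community gene pools plus a shared background pool.
#' Each pathway draws `round(within_fraction * set_size)` genes from its
#' community's pool and the rest from the background, so inter-community
#' similarity arises only through the background and `within_fraction` is
#' the single difficulty knob (1 gives disconnected communities; values
#' near `1/K` erase the structure). Pathway names are a database tag, a
#' community-specific contiguous 3-token core, and a unique suffix, so the
#' labelling stage has a known ground truth.
#'
#' @param K number of planted communities.
#' @param pathways_per_community gene sets per community.
#' @param pool_size genes in each community pool.
#' @param background_size genes in the shared background pool.
#' @param set_size genes per pathway.
#' @param within_fraction expected fraction of a pathway's genes drawn
#'   from its own community pool, in (0, 1].
#' @param n_sources number of simulated source databases (tags assigned
#'   round-robin).
#' @param seed integer seed; generation is fully determined by it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(K = 5, pathways_per_community = 20,
                           pool_size = 200, background_size = 2000,
                           set_size = 40, within_fraction = 0.8,
                           n_sources = 2, seed = 7) {
  stopifnot(K >= 1, pathways_per_community >= 1, pool_size >= 1,
            background_size >= 0, set_size >= 1,
            within_fraction > 0, within_fraction <= 1,
            n_sources >= 1)
  n_within <- round(within_fraction * set_size)
  if (n_within > pool_size)
    stop("community pool too small for the requested within-community draw")
  if (set_size - n_within > background_size)
    stop("background pool too small for the requested background draw")
  if (3 * K > length(CORE_VOCAB))
    stop("not enough core vocabulary for ", K, " communities")
  structure(list(K = K, pathways_per_community = pathways_per_community,
                 pool_size = pool_size, background_size = background_size,
                 set_size = set_size, within_fraction = within_fraction,
                 n_sources = n_sources, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic collection with planted communities
#'
#' @param spec a [synthetic_spec()].
#' @return list with `collection` (a [geneset_collection()]), `truth` (a
#'   [partition()] of the planted memberships), `categories` (named
#'   character vector pathway -> planted label, usable as a curated
#'   category map), and `vocabulary` (list: community label -> its 3-token
#'   name core).
#' @export
generate_collection <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, generate_collection_impl(spec))
}

generate_collection_impl <- function(spec) {
  source_tags <- rep_len(c("KEGG", "REACTOME", "GOBP", "GOMF",
                           paste0("DB", seq_len(max(0, spec$n_sources - 4)))),
                         spec$n_sources)
  pools <- lapply(seq_len(spec$K), function(c_)
    sprintf("C%02dG%04d", c_, seq_len(spec$pool_size)))
  background <- sprintf("BGG%05d", seq_len(spec$background_size))
  cores <- lapply(seq_len(spec$K), function(c_)
    CORE_VOCAB[(3 * (c_ - 1) + 1):(3 * c_)])
  n_within <- round(spec$within_fraction * spec$set_size)
  n_bg <- spec$set_size - n_within

  sets <- list()
  names_disp <- character(0)
  truth <- character(0)
  counter <- 0L
  for (c_ in seq_len(spec$K)) {
    for (p_ in seq_len(spec$pathways_per_community)) {
      counter <- counter + 1L
      own <- sample(pools[[c_]], n_within)
      bg <- if (n_bg > 0) sample(background, n_bg) else character(0)
      tag <- source_tags[((counter - 1L) %% spec$n_sources) + 1L]
      core <- toupper(paste(cores[[c_]], collapse = "_"))
      id <- sprintf("%s_%s_SET%03d", tag, core, counter)
      sets[[id]] <- c(own, bg)
      names_disp <- c(names_disp, id)
      truth <- c(truth, sprintf("community_%d", c_))
    }
  }
  ids <- names(sets)
  collection <- geneset_collection(
    sets,
    sources = infer_source(ids),
    universe = c(unlist(pools, use.names = FALSE), background)
  )
  labels <- vapply(seq_len(spec$K), function(c_)
    paste(cores[[c_]], collapse = " "), character(1))
  categories <- stats::setNames(
    labels[as.integer(sub("community_", "", truth))], ids)
  list(
    collection = collection,
    truth = partition(stats::setNames(truth, ids), resolution = 1,
                      seed = spec$seed),
    categories = categories,
    vocabulary = stats::setNames(cores, labels)
  )
}

#' Write a synthetic dataset to disk
#'
#' Emits the collection as GMT, the planted truth partition as TSV, the
#' category map as two-column TSV, and the spec as YAML (when the yaml
#' package is available) or JSON. Output is byte-identical for a fixed
#' spec.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic_dataset <- function(spec, dir) {
  dataset <- generate_collection(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gmt = file.path(dir, "synthetic.gmt"),
             truth = file.path(dir, "truth_partition.tsv"),
             categories = file.path(dir, "categories.tsv"),
             spec = file.path(dir, "spec.yaml"))
  write_gmt(dataset$collection, paths[["gmt"]])
  write_partition_tsv(dataset$truth, paths[["truth"]])
  writeLines(sprintf("%s\t%s", names(dataset$categories),
                     dataset$categories), paths[["categories"]])
  fields <- unclass(spec)
  if (requireNamespace("yaml", quietly = TRUE)) {
    writeLines(yaml::as.yaml(fields), paths[["spec"]])
  } else {
    paths[["spec"]] <- file.path(dir, "spec.json")
    jsonlite::write_json(fields, paths[["spec"]], auto_unbox = TRUE)
  }
  invisible(paths)
}
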