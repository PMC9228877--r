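#' Normalized mutual information between two labellings
#'
#' `NMI = I(A;B) / mean(H(A), H(B))` with natural-log entropies over the
#' joint contingency table. Conventions for degenerate cases: 1 when both
#' labellings are single-cluster (they agree perfectly), 0 when exactly one
#' has zero entropy (knowing a constant labelling conveys nothing).
#'
#' @param labels_a,labels_b vectors of cluster labels over the same items;
#'   if named, they are aligned by name and the item sets must match.
#' @param normalization denominator: arithmetic `"mean"` of the entropies
#'   (default), `"min"`, `"max"`, or `"geometric"` mean.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(labels_a, labels_b,
                normalization = c("mean", "min", "max", "geometric")) {
  normalization <- match.arg(normalization)
  na <- names(labels_a); nb <- names(labels_b)
  if (!is.null(na) && !is.null(nb)) {
    if (!setequal(na, nb)) stop("labellings cover different item sets")
    labels_b <- labels_b[na]
  } else if (length(labels_a) != length(labels_b)) {
    stop("labellings cover different item sets")
  }
  n <- length(labels_a)
  if (n == 0L) stop("empty labellings")
  tab <- table(as.character(labels_a), as.character(labels_b))
  pij <- tab / n
  pa <- rowSums(pij)
  pb <- colSums(pij)
  ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  outer_p <- outer(pa, pb)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer_p[nz]))
  denom <- switch(normalization,
                  mean = (ha + hb) / 2,
                  min = min(ha, hb),
                  max = max(ha, hb),
                  geometric = sqrt(ha * hb))
  min(1, max(0, mi / denom))
}

#' Score a partition against curated categories
#'
#' NMI restricted to the pathways present in both the partition and the
#' category map; unlabelled pathways are excluded and counted.
#'
#' @param partition a [partition()].
#' @param categories named character vector (pathway id -> category), as
#'   returned by [read_category_map()].
#' @param ... passed to [nmi()].
#' @return list with `nmi`, `n_scored`, `n_excluded`.
#' @export
evaluate_against_categories <- function(partition, categories, ...) {
  stopifnot(inherits(partition, "partition"))
  ids <- intersect(names(partition$assignment), names(categories))
  if (length(ids) == 0L)
    stop("no pathway appears in both the partition and the category map")
  list(nmi = nmi(partition$assignment[ids], categories[ids], ...),
       n_scored = length(ids),
       n_excluded = length(partition$assignment) - length(ids))
}

#' Per-pathway maximum overlap fraction (redundancy profile)
#'
#' For each pathway A, the maximum over eligible partners B of
#' `|A intersect B| / |A|` — the fraction of A's genes recoverable from a
#' single other pathway. Scope restricts partners to the same source
#' database (`"within"`), a different one (`"cross"`), or any (`"any"`).
#' High values reveal redundancy within and across databases.
#'
#' @param collection a [geneset_collection()] with at least 2 pathways.
#' @param scope `"within"`, `"cross"`, or `"any"`.
#' @return data frame: `id`, `best_partner` (`NA` when no eligible
#'   partner), `fraction` (0 with `no_partner = TRUE` in that case),
#'   `no_partner`.
#' @export
max_overlap_fraction <- function(collection, scope = c("within", "cross",
                                                       "any")) {
  stopifnot(inherits(collection, "geneset_collection"))
  scope <- match.arg(scope)
  n <- length(collection$ids)
  if (n < 2L) stop("need at least 2 pathways")
  inc <- incidence_matrix(collection)
  ov <- as.matrix(Matrix::crossprod(inc))
  diag(ov) <- NA
  src <- collection$sources
  eligible <- switch(scope,
                     within = outer(src, src, `==`),
                     cross = outer(src, src, `!=`),
                     any = matrix(TRUE, n, n))
  ov[!eligible] <- NA
  sizes <- lengths(collection$genes)
  best <- apply(ov, 1L, function(row) {
    if (all(is.na(row))) NA_integer_ else which.max(row)
  })
  no_partner <- is.na(best)
  frac <- ifelse(no_partner, 0,
                 ov[cbind(seq_len(n), ifelse(no_partner, 1L, best))] / sizes)
  data.frame(id = collection$ids,
             best_partner = ifelse(no_partner, NA_character_,
                                   collection$ids[best]),
             fraction = unname(frac),
             no_partner = unname(no_partner))
}

#' Per-community gene over-representation
#'
#' For each gene g and community C, the one-sided hypergeometric p-value of
#' drawing at least the observed number of C's pathways containing g, when
#' |C| pathways are drawn from all N pathways of which K contain g.
#' Adjusted across all (gene, community) tests.
#'
#' @param collection a [geneset_collection()].
#' @param partition a [partition()] covering the collection's pathways.
#' @param alpha significance threshold on the adjusted p-value.
#' @param method multiple-testing adjustment passed to
#'   [stats::p.adjust()]; default `"BH"` (Benjamini-Hochberg), with
#'   `"bonferroni"` the conservative alternative.
#' @return data frame: `gene`, `community`, `x` (members containing the
#'   gene), `K` (pathways containing it anywhere), `n` (community size),
#'   `N` (total pathways), `p_raw`, `p_adjusted`, `significant`.
#' @export
gene_overrepresentation <- function(collection, partition, alpha = 0.05,
                                    method = "BH") {
  stopifnot(inherits(collection, "geneset_collection"),
            inherits(partition, "partition"))
  comm <- partition$assignment[collection$ids]
  if (anyNA(comm)) stop("partition does not cover all pathways")
  inc <- incidence_matrix(collection)          # genes x pathways
  cid <- sort(unique(comm))
  member <- vapply(cid, function(c_) comm == c_,
                   logical(length(collection$ids)))
  x <- as.matrix(inc %*% member)               # gene x community counts
  K <- Matrix::rowSums(inc)
  n_sizes <- colSums(member)
  N <- length(collection$ids)
  genes <- rownames(inc)
  df <- data.frame(
    gene = rep(genes, times = length(cid)),
    community = rep(cid, each = length(genes)),
    x = as.vector(x),
    K = rep(unname(K), times = length(cid)),
    n = rep(n_sizes, each = length(genes)),
    N = N
  )
  df$p_raw <- stats::phyper(df$x - 1, df$K, N - df$K, df$n,
                            lower.tail = FALSE)
  df$p_adjusted <- stats::p.adjust(df$p_raw, method = method)
  df$significant <- df$p_adjusted <= alpha
  df <- df[order(df$p_adjusted, df$p_raw, df$gene, df$community), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Agreement between query assignments and founder membership
#'
#' For reference groups (e.g. summary gene sets with known founder
#' pathways), compares the community assigned by querying each group
#' against the community containing most of its founders. A group agrees
#' when its assigned community is an argmax of the founder counts (ties
#' count as agreement); the rank of the assigned community among founder
#' counts is also reported (competition ranking: rank 1 = argmax).
#'
#' @param query_assignments named vector: group -> assigned community id.
#' @param founder_membership named list: group -> named vector of founder
#'   counts per community id.
#' @return object of class `agreement_report`: `per_group` data frame
#'   (`group`, `assigned`, `top_founder`, `agree`, `rank`) and
#'   `summary` (fraction of groups agreeing). Groups without founder
#'   counts are excluded with a warning.
#' @export
assignment_agreement <- function(query_assignments, founder_membership) {
  groups <- names(query_assignments)
  if (is.null(groups)) stop("query_assignments must be named by group")
  has_founders <- vapply(groups, function(g) {
    fc <- founder_membership[[g]]
    !is.null(fc) && length(fc) > 0L && sum(fc) > 0
  }, logical(1))
  if (any(!has_founders)) {
    warning("groups without founder counts excluded: ",
            paste(groups[!has_founders], collapse = ", "))
    groups <- groups[has_founders]
  }
  if (length(groups) == 0L) stop("no group has founder counts")
  rows <- lapply(groups, function(g) {
    fc <- founder_membership[[g]]
    assigned <- as.character(query_assignments[[g]])
    top <- names(fc)[fc == max(fc)]
    cnt <- fc[match(assigned, names(fc))]
    cnt <- if (is.na(cnt)) 0 else cnt
    rank <- sum(fc > cnt) + 1L
    data.frame(group = g, assigned = assigned,
               top_founder = top[order(top)][1L],
               agree = assigned %in% top, rank = rank)
  })
  per_group <- do.call(rbind, rows)
  rownames(per_group) <- NULL
  structure(list(per_group = per_group,
                 summary = mean(per_group$agree)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "agreement_report: %d groups, %.1f%% assigned to the top-founder community\n",
    nrow(x$per_group), 100 * x$summary))
  invisible(x)
}
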