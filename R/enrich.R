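#' One-sided hypergeometric over-representation test
#'
#' Exact upper-tail probability \eqn{P(X \ge k)} for
#' \eqn{X \sim \mathrm{Hypergeom}(N, K, n)} by direct summation of the
#' probability mass, with fold enrichment \eqn{(k/n)/(K/N)}.
#'
#' @param k hits: genes of the list that are in the set.
#' @param n list size.
#' @param K set size.
#' @param N universe size.
#' @return list `p`, `fold` (NA when k = 0).
#' @export
hypergeom_test <- function(k, n, K, N) {
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > min(n, K) || n > N || K > N)
    stop("inconsistent counts for hypergeometric test")
  support <- k:min(n, K)
  p <- min(1, sum(stats::dhyper(support, K, N - K, n)))
  fold <- if (k == 0) NA_real_ else (k / n) / (K / N)
  list(p = p, fold = fold)
}

#' Over-representation of a gene list across a set collection
#'
#' @param gene_list character vector of gene ids (duplicates removed; ids
#'   outside the universe are dropped with a message).
#' @param collection list with `sets` (named list of character vectors) and
#'   `universe` (character vector), e.g. from [read_gmt()] plus a universe.
#' @return data.frame set, k, K, n, N, p, fold, q, ordered by p then set
#'   name; empty (with a warning) if the list is empty after intersection.
#' @export
enrich_collection <- function(gene_list, collection) {
  universe <- unique(collection$universe)
  N <- length(universe)
  gene_list <- unique(gene_list)
  dropped <- setdiff(gene_list, universe)
  if (length(dropped))
    message(length(dropped), " gene(s) outside the universe dropped")
  gene_list <- intersect(gene_list, universe)
  n <- length(gene_list)
  if (n == 0) {
    warning("empty gene list after intersecting with the universe")
    return(data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      fold = numeric(0), q = numeric(0)))
  }
  sets <- lapply(collection$sets, function(s) intersect(unique(s), universe))
  sets <- sets[lengths(sets) > 0]
  rows <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    k <- length(intersect(gene_list, sets[[nm]]))
    ht <- hypergeom_test(k, n, K, N)
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               p = ht$p, fold = ht$fold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}

#' Module-by-stage enrichment of flagged genes
#'
#' For each stage (names of `flagged_genes_by_stage`), tests every
#' co-expression module for over-representation of that stage's flagged
#' genes, BH-correcting across modules within stage.
#'
#' @param assignment a [merge_modules()] result (or any list with a named
#'   `labels` character vector gene -> module).
#' @param flagged_genes_by_stage named list of character vectors.
#' @param include_grey test the unassigned ("grey") pool too.
#' @return data.frame stage, module (set), k, K, n, N, p, fold, q.
#' @export
module_set_enrichment <- function(assignment, flagged_genes_by_stage,
                                  include_grey = FALSE) {
  labels <- assignment$labels
  universe <- names(labels)
  mods <- split(universe, labels)
  if (!include_grey) mods <- mods[names(mods) != "grey"]
  out <- list()
  for (stage in names(flagged_genes_by_stage)) {
    genes <- flagged_genes_by_stage[[stage]]
    if (length(intersect(genes, universe)) == 0) next
    tab <- enrich_collection(genes, list(sets = mods, universe = universe))
    if (nrow(tab) == 0) next
    tab <- cbind(stage = stage, tab)
    out[[stage]] <- tab
  }
  if (length(out) == 0)
    return(data.frame(stage = character(0), set = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), fold = numeric(0),
                      q = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
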