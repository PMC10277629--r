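## Module label palette, in the conventional size-rank order used by
## co-expression tooling ("grey" reserved for unassigned genes).
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

## Biweight-midcorrelation weights for one gene's sample vector. Outlier
## capping: if more than max_p_outliers of a tail would get zero weight
## (|u| >= 1), rescale that side so the tail quantile lands at |u| = 1.
bicor_prep <- function(x, max_p_outliers = 0.1) {
  med <- stats::median(x)
  madx <- stats::median(abs(x - med))
  if (madx == 0) return(NULL)  # caller falls back to Pearson
  u <- (x - med) / (9 * madx)
  ql <- stats::quantile(x, max_p_outliers, names = FALSE)
  qu <- stats::quantile(x, 1 - max_p_outliers, names = FALSE)
  ul <- (ql - med) / (9 * madx)
  uu <- (qu - med) / (9 * madx)
  neg <- u < 0; pos <- u > 0
  if (ul < -1) u[neg] <- u[neg] / abs(ul)
  if (uu > 1) u[pos] <- u[pos] / uu
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xc <- (x - med) * w
  nrm <- sqrt(sum(xc^2))
  if (nrm == 0) return(NULL)
  xc / nrm
}

#' Biweight midcorrelation matrix
#'
#' Robust correlation of every pair of gene expression profiles using Tukey
#' biweights around the median, with side-specific capping so that at most
#' `max_p_outliers` of either tail is fully down-weighted. Genes whose
#' median absolute deviation is zero (or whose weighted vector degenerates)
#' fall back to Pearson for all their pairs, with a message.
#'
#' @param expr genes x samples matrix of log-normalized expression, at least
#'   4 samples.
#' @param max_p_outliers maximum fraction per tail allowed zero weight.
#' @return genes x genes correlation matrix with unit diagonal.
#' @export
bicor_matrix <- function(expr, max_p_outliers = 0.1) {
  if (ncol(expr) < 4) stop("need at least 4 samples")
  n_g <- nrow(expr)
  prep <- lapply(seq_len(n_g), function(g) bicor_prep(expr[g, ], max_p_outliers))
  fallback <- vapply(prep, is.null, logical(1))
  if (any(fallback))
    message(sum(fallback), " gene(s) with zero MAD; Pearson fallback used")
  W <- matrix(0, ncol(expr), n_g)
  for (g in which(!fallback)) W[, g] <- prep[[g]]
  for (g in which(fallback)) {
    x <- expr[g, ]
    xc <- x - mean(x)
    nrm <- sqrt(sum(xc^2))
    W[, g] <- if (nrm > 0) xc / nrm else 0
  }
  if (any(fallback)) {
    ## pairs touching a fallback gene must be Pearson on BOTH sides
    Wp <- apply(expr, 1, function(x) {
      xc <- x - mean(x); nrm <- sqrt(sum(xc^2))
      if (nrm > 0) xc / nrm else rep(0, length(x))
    })
    C <- crossprod(W)
    Cp <- crossprod(Wp)
    C[fallback, ] <- Cp[fallback, ]
    C[, fallback] <- Cp[, fallback]
  } else {
    C <- crossprod(W)
  }
  C <- pmin(pmax(C, -1), 1)
  diag(C) <- 1
  dimnames(C) <- list(rownames(expr), rownames(expr))
  C
}

#' Signed-hybrid soft-threshold adjacency
#'
#' \eqn{a_{ij} = \mathrm{cor}_{ij}^\beta} for positive correlations, 0 for
#' negative; unit diagonal.
#'
#' @param cor correlation matrix, entries in `[-1, 1]`.
#' @param beta soft-threshold power (> 0; default 5).
#' @return adjacency matrix in `[0, 1]`.
#' @export
adjacency_signed_hybrid <- function(cor, beta = 5) {
  if (beta <= 0) stop("beta must be > 0")
  if (any(cor < -1 - 1e-12 | cor > 1 + 1e-12)) stop("correlations outside [-1, 1]")
  a <- ifelse(cor > 0, cor^beta, 0)
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' \eqn{\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#' {\min(k_i, k_j) + 1 - a_{ij}}} with connectivity
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}; unit diagonal.
#'
#' @param adjacency symmetric matrix in `[0, 1]` with unit diagonal.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) stop("adjacency must be symmetric")
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a  # (i,j) entry: sum_u a_iu a_uj (u != i,j since diag 0) + a_ij
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect preliminary co-expression modules
#'
#' Average-linkage hierarchical clustering of genes on 1 - TOM, cut
#' statically at `cut_height`; clusters smaller than `min_module_size` are
#' relabeled "grey" (unassigned). Surviving modules are named by decreasing
#' size using the conventional color ordering.
#'
#' @param tom TOM similarity from [tom_similarity()].
#' @param min_module_size smallest retained module.
#' @param cut_height static tree-cut height on the 1 - TOM dendrogram.
#' @return named character vector gene -> module label.
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.995) {
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(raw))
  if (length(big)) {
    ord <- big[order(-sizes[big], as.integer(big))]
    palette <- c(MODULE_COLORS[MODULE_COLORS != "grey"],
                 paste0("module", seq_along(ord)))
    for (i in seq_along(ord))
      labels[raw == as.integer(ord[i])] <- palette[i]
  } else {
    warning("no module reaches min_module_size; all genes grey")
  }
  stats::setNames(labels, rownames(tom))
}

## first right-singular vector of the row-standardized module submatrix,
## sign-fixed so the average correlation with member profiles is positive
module_eigengene <- function(expr, genes) {
  sub <- expr[genes, , drop = FALSE]
  Z <- t(scale(t(sub)))
  Z[!is.finite(Z)] <- 0
  sv <- svd(Z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  if (mean(stats::cor(e, t(sub))) < 0) e <- -e
  e / sqrt(sum(e^2))
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest module pair whenever the eigengene
#' dissimilarity 1 - cor falls below `merge_cut`, recomputing eigengenes
#' after each merge, until all pairwise eigengene correlations are below
#' 1 - merge_cut.
#'
#' @param expr genes x samples log-normalized expression (the matrix the
#'   modules were detected on).
#' @param labels named gene -> module vector from [detect_modules()].
#' @param merge_cut eigengene dissimilarity threshold (default 0.25).
#' @return list of class "module_assignment": `labels`, `eigengenes`
#'   (samples x modules, unit-norm columns; grey excluded), `merge_cut`,
#'   `merges` (count).
#' @export
merge_modules <- function(expr, labels, merge_cut = 0.25) {
  labels <- labels[rownames(expr)]
  n_merges <- 0L
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) break
    eg <- vapply(mods, function(m) module_eigengene(expr, names(labels)[labels == m]),
                 numeric(ncol(expr)))
    C <- stats::cor(eg)
    diag(C) <- -Inf
    best <- which(C == max(C), arr.ind = TRUE)[1, ]
    if (1 - max(C) >= merge_cut) break
    keep <- mods[min(best)]; drop <- mods[max(best)]
    labels[labels == drop] <- keep
    n_merges <- n_merges + 1L
  }
  mods <- setdiff(unique(labels), "grey")
  eigengenes <- if (length(mods)) {
    eg <- vapply(mods, function(m) module_eigengene(expr, names(labels)[labels == m]),
                 numeric(ncol(expr)))
    colnames(eg) <- mods
    rownames(eg) <- colnames(expr)
    eg
  } else matrix(0, ncol(expr), 0, dimnames = list(colnames(expr), NULL))
  structure(list(labels = labels, eigengenes = eigengenes,
                 merge_cut = merge_cut, merges = n_merges),
            class = "module_assignment")
}

#' Full co-expression module pipeline
#'
#' bicor -> signed-hybrid adjacency -> TOM -> average-linkage static-cut
#' module detection -> eigengene merging.
#'
#' @param expr genes x samples log-normalized expression.
#' @param beta soft-threshold power.
#' @param max_p_outliers bicor tail cap.
#' @param min_module_size,cut_height,merge_cut detection/merging parameters.
#' @return a [merge_modules()] result.
#' @export
coexpression_modules <- function(expr, beta = 5, max_p_outliers = 0.1,
                                 min_module_size = 30, cut_height = 0.995,
                                 merge_cut = 0.25) {
  C <- bicor_matrix(expr, max_p_outliers = max_p_outliers)
  A <- adjacency_signed_hybrid(C, beta = beta)
  tom <- tom_similarity(A)
  labels <- detect_modules(tom, min_module_size = min_module_size,
                           cut_height = cut_height)
  merge_modules(expr, labels, merge_cut = merge_cut)
}
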