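#' Estimate cell-type proportions by nonnegative least squares
#'
#' For every sample, solves \eqn{\min_x \|S x - b\|^2, x \ge 0} over the
#' genes common to the bulk matrix and the signature, with the signature
#' columns and the bulk vector standardized (zero mean, unit SD) before the
#' fit, then renormalizes x to the simplex, yielding relative proportions.
#'
#' @param bulk_expression genes x samples matrix on a linear scale (e.g.
#'   CPM from [cpm_normalized()]).
#' @param signature genes x cell-types reference expression, linear scale.
#' @return list with `proportions` (samples x cell types, rows summing to 1)
#'   and `residuals` (per-sample residual norm of the standardized fit).
#' @export
estimate_proportions <- function(bulk_expression, signature) {
  common <- intersect(rownames(bulk_expression), rownames(signature))
  if (length(common) < ncol(signature))
    stop("common gene set smaller than the number of cell types")
  S0 <- signature[common, , drop = FALSE]
  col_sd <- apply(S0, 2, stats::sd)
  col_sd[col_sd == 0] <- 1
  S <- sweep(sweep(S0, 2, colMeans(S0), "-"), 2, col_sd, "/")
  B <- bulk_expression[common, , drop = FALSE]
  n_types <- ncol(signature)
  props <- matrix(NA_real_, ncol(B), n_types,
                  dimnames = list(colnames(B), colnames(signature)))
  resid <- stats::setNames(numeric(ncol(B)), colnames(B))
  for (k in seq_len(ncol(B))) {
    b <- B[, k]
    sdb <- stats::sd(b)
    b <- if (sdb > 0) (b - mean(b)) / sdb else b - mean(b)
    fit <- pracma::lsqnonneg(S, b)
    ## the standardized-space solution carries a factor sd_c (and 1/sd_b);
    ## undo the column scaling so the simplex renormalization is unbiased
    x <- fit$x / col_sd
    resid[k] <- sqrt(max(fit$resid.norm, 0))
    if (sum(x) <= 0) {
      warning("zero NNLS solution for sample ", colnames(B)[k],
              "; returning uniform proportions")
      x <- rep(1, n_types)
    }
    props[k, ] <- x / sum(x)
  }
  list(proportions = props, residuals = resid)
}

#' Principal components of estimated cell-type proportions
#'
#' Column-centers the proportions and decomposes them by SVD, condensing the
#' joint movement of all cell types into a few sample-level scores suitable
#' as regression covariates.
#'
#' @param estimates result of [estimate_proportions()], or a samples x types
#'   proportion matrix.
#' @return list with `scores` (samples x PCs, zero-mean columns),
#'   `var_explained` (non-increasing, summing to 1 over returned PCs) and
#'   `n_pcs`. Constant proportions yield zero PCs with a warning.
#' @export
proportion_pcs <- function(estimates) {
  P <- if (is.list(estimates)) estimates$proportions else estimates
  if (nrow(P) < 3) stop("need at least 3 samples")
  X <- scale(P, center = TRUE, scale = FALSE)
  sv <- svd(X)
  tol <- max(sv$d) * 1e-8
  keep <- which(sv$d > tol & sv$d > 0)
  if (max(sv$d) == 0 || length(keep) == 0) {
    warning("proportions constant across samples; no PCs")
    return(list(scores = matrix(0, nrow(P), 0,
                                dimnames = list(rownames(P), NULL)),
                var_explained = numeric(0), n_pcs = 0L))
  }
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  dimnames(scores) <- list(rownames(P), paste0("PC", keep))
  ve <- sv$d[keep]^2 / sum(sv$d^2)
  list(scores = scores, var_explained = ve, n_pcs = length(keep))
}

#' Select proportion PCs associated with gene expression
#'
#' Each PC score is tested, one gene at a time, as the sole predictor of
#' log-normalized expression; a PC is retained as a model covariate iff the
#' fraction of genes significant after BH correction exceeds
#' `min_genes_fraction`.
#'
#' @param pcs result of [proportion_pcs()].
#' @param log_expression genes x samples log-normalized expression with the
#'   same samples as the PC scores.
#' @param fdr BH threshold per gene.
#' @param min_genes_fraction minimum fraction of significant genes.
#' @return integer indices of selected PCs, in variance order.
#' @export
select_pcs <- function(pcs, log_expression, fdr = 0.05,
                       min_genes_fraction = 0.05) {
  if (pcs$n_pcs == 0) return(integer(0))
  if (!identical(rownames(pcs$scores), colnames(log_expression)))
    stop("PC scores and expression matrix cover different samples")
  n <- ncol(log_expression)
  sel <- integer(0)
  for (j in seq_len(pcs$n_pcs)) {
    s <- pcs$scores[, j]
    r <- suppressWarnings(as.vector(stats::cor(s, t(log_expression))))
    r[!is.finite(r)] <- NA
    tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    q <- bh_fdr(p)
    frac <- mean(q < fdr, na.rm = TRUE)
    if (is.finite(frac) && frac > min_genes_fraction) sel <- c(sel, j)
  }
  sel
}

#' Paired tests for proportion changes against baseline
#'
#' For each cell type and non-baseline timepoint, a paired Wilcoxon
#' signed-rank test of that type's proportions against the same subjects'
#' baseline values. Descriptive companion to the deconvolution output.
#'
#' @param estimates result of [estimate_proportions()].
#' @param metadata data.frame with sample_id, subject_id, timepoint.
#' @param ref baseline timepoint (default "T0").
#' @return data.frame cell_type, timepoint, median_ref, median_t, p.
#' @export
proportion_change_tests <- function(estimates, metadata, ref = "T0") {
  P <- estimates$proportions
  md <- metadata[match(rownames(P), metadata$sample_id), ]
  tps <- setdiff(intersect(TIMEPOINT_LEVELS, unique(md$timepoint)), ref)
  out <- list()
  for (ct in colnames(P)) {
    for (tp in tps) {
      md_ref <- md[md$timepoint == ref, ]
      md_t <- md[md$timepoint == tp, ]
      subj <- intersect(md_ref$subject_id, md_t$subject_id)
      if (length(subj) < 3) next
      a <- P[md_ref$sample_id[match(subj, md_ref$subject_id)], ct]
      b <- P[md_t$sample_id[match(subj, md_t$subject_id)], ct]
      pv <- tryCatch(stats::wilcox.test(a, b, paired = TRUE)$p.value,
                     error = function(e) NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        cell_type = ct, timepoint = tp,
        median_ref = stats::median(a), median_t = stats::median(b),
        p = pv, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
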