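#' Default excluded gene types
#'
#' Small/structural RNA classes and pseudogenes routinely removed from
#' whole-blood gene-level count matrices before differential analysis.
#' @export
DEFAULT_EXCLUDED_TYPES <- c("rRNA", "pseudogene", "misc_RNA", "Mt_tRNA",
                            "scaRNA", "snRNA", "snoRNA", "TEC")

gene_types_of <- function(counts) {
  gt <- attr(counts, "gene_type")
  if (is.null(gt)) stop("counts has no 'gene_type' annotation")
  gt
}

subset_genes <- function(counts, keep) {
  gt <- attr(counts, "gene_type")
  out <- counts[keep, , drop = FALSE]
  if (!is.null(gt)) attr(out, "gene_type") <- gt[rownames(out)]
  out
}

#' Remove genes of excluded biotypes
#'
#' @param counts genes x samples count matrix carrying a `gene_type`
#'   attribute (named character vector).
#' @param excluded_types biotypes to drop; defaults to
#'   [DEFAULT_EXCLUDED_TYPES].
#' @return the count matrix without the excluded genes, order preserved.
#' @export
filter_gene_types <- function(counts, excluded_types = DEFAULT_EXCLUDED_TYPES) {
  gt <- gene_types_of(counts)
  if (length(excluded_types) == 0) return(counts)
  keep <- rownames(counts)[!(gt[rownames(counts)] %in% excluded_types)]
  subset_genes(counts, keep)
}

#' Remove genes with low expression
#'
#' Keeps gene g iff its raw (pre-normalization) counts-per-million exceed
#' `cpm_numerator / L` in at least `min_samples` samples, where L is the
#' minimum library size in millions. With the defaults this is the common
#' "CPM > 10/L in 8 or more samples" rule.
#'
#' @param counts genes x samples count matrix.
#' @param cpm_numerator numerator of the adaptive CPM threshold.
#' @param min_samples minimum number of samples above threshold.
#' @return filtered count matrix (warns, rather than errors, if nothing
#'   survives).
#' @export
filter_low_expression <- function(counts, cpm_numerator = 10, min_samples = 8) {
  if (ncol(counts) < min_samples)
    stop("fewer than min_samples samples present")
  N <- colSums(counts)
  L <- min(N) / 1e6
  thr <- cpm_numerator / L
  cpm <- sweep(counts, 2, N, "/") * 1e6
  keep <- rownames(counts)[rowSums(cpm > thr) >= min_samples]
  if (length(keep) == 0) warning("all genes removed by expression filter")
  subset_genes(counts, keep)
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes per-sample scaling factors from a doubly trimmed, precision-
#' weighted mean of gene-wise log2 expression ratios against a reference
#' sample (the sample whose 75th-percentile CPM is closest to the mean
#' 75th percentile). For sample k vs reference r, over genes with positive
#' counts in both, \eqn{M_g = \log_2\frac{y_{gk}/N_k}{y_{gr}/N_r}} and
#' \eqn{A_g = \tfrac12 \log_2\left(\frac{y_{gk}}{N_k}\frac{y_{gr}}{N_r}\right)};
#' the top and bottom `trim_m` fraction by M and `trim_a` fraction by A are
#' discarded, and the factor is
#' \eqn{f_k = 2^{\sum w_g M_g / \sum w_g}} with delta-method weights
#' \eqn{w_g^{-1} = \frac{N_k-y_{gk}}{N_k y_{gk}} + \frac{N_r-y_{gr}}{N_r y_{gr}}}.
#' Factors are rescaled to geometric mean 1. Zeros are excluded from the M/A
#' computation rather than continuity-corrected.
#'
#' @param counts genes x samples count matrix.
#' @param trim_m two-sided trim fraction on M (default 0.30).
#' @param trim_a two-sided trim fraction on A (default 0.05).
#' @return list with `factors` (named, geometric mean 1), `lib_sizes`
#'   (named column sums) and `ref_sample`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  if (ncol(counts) < 2) stop("need at least 2 samples")
  N <- colSums(counts)
  cpm <- sweep(counts, 2, N, "/") * 1e6
  f75 <- apply(cpm, 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  yr <- counts[, ref]
  f <- vapply(seq_len(ncol(counts)), function(k) {
    if (k == ref) return(1)
    tmm_pair_factor(counts[, k], yr, N[k], N[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  list(factors = stats::setNames(f, colnames(counts)),
       lib_sizes = N, ref_sample = colnames(counts)[ref])
}

## factor of one sample against the reference; exported logic kept internal
tmm_pair_factor <- function(yk, yr, Nk, Nr, trim_m, trim_a) {
  pos <- yk > 0 & yr > 0
  yk <- yk[pos]; yr <- yr[pos]
  M <- log2((yk / Nk) / (yr / Nr))
  A <- 0.5 * log2((yk / Nk) * (yr / Nr))
  w <- 1 / ((Nk - yk) / (Nk * yk) + (Nr - yr) / (Nr * yr))
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (sum(keep) < 10) {
    warning("fewer than 10 genes survive TMM trimming; factor set to 1")
    return(1)
  }
  2 ^ (sum(w[keep] * M[keep]) / sum(w[keep]))
}

#' (Log-)CPM on TMM-effective library sizes
#'
#' @param counts genes x samples count matrix.
#' @param factors result of [tmm_factors()] on the same samples.
#' @param log return log2 values.
#' @param prior prior count added before the log; scaled per sample in
#'   proportion to the effective library size so that the log-CPM of a zero
#'   count is constant across samples.
#' @return numeric matrix of (log-)normalized expression.
#' @export
cpm_normalized <- function(counts, factors, log = FALSE, prior = 0.5) {
  if (!identical(colnames(counts), names(factors$factors)))
    stop("factors do not match the samples of counts")
  eff <- factors$lib_sizes * factors$factors
  if (!log) return(sweep(counts, 2, eff, "/") * 1e6)
  pr <- prior * eff / mean(eff)
  log2(sweep(sweep(counts, 2, pr, "+"), 2, eff, "/") * 1e6)
}
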