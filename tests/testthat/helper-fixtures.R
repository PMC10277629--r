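## Shared fixtures and independent oracles for the test suite.

## Small cohort reused across tests (built once per test run).
.small_cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function(seed = 1, ...) {
  key <- paste(seed, deparse(list(...)), collapse = "_")
  if (is.null(.small_cohort_cache[[key]])) {
    .small_cohort_cache[[key]] <- simulate_cohort(
      n_subjects = 14, n_genes = 400, n_cell_types = 8,
      markers_per_type = 10, seed = seed, ...)
  }
  .small_cohort_cache[[key]]
}

## Default-scale cohort (2,000 genes) at fixed dispersion 0.05, shared by the
## deconvolution tests; built once.
default_phi05_cohort <- function() {
  if (is.null(.small_cohort_cache$default_phi05)) {
    .small_cohort_cache$default_phi05 <- simulate_cohort(
      phi_range = c(0.05, 0.0500001), seed = 21)
  }
  .small_cohort_cache$default_phi05
}

## True per-sample proportions of a cohort, rows matching sample ids.
true_proportions <- function(sim, samples) {
  comps <- sim$compositions
  P <- do.call(rbind, lapply(dimnames(comps)[[2]], function(t) comps[, t, ]))
  rownames(P) <- as.vector(outer(dimnames(comps)[[1]], dimnames(comps)[[2]],
                                 paste, sep = "_"))
  P[samples, , drop = FALSE]
}

preprocess_cohort <- function(sim) {
  counts <- filter_low_expression(filter_gene_types(sim$counts), 10, 8)
  factors <- tmm_factors(counts)
  list(counts = counts, factors = factors,
       cpm = cpm_normalized(counts, factors),
       logcpm = cpm_normalized(counts, factors, log = TRUE))
}

## Rand index between two partitions (label vectors).
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  agree <- same_a == same_b
  (sum(agree[upper.tri(agree)])) / choose(n, 2)
}

## Literal transcription of the TMM factor definition for one sample vs a
## reference: M/A over doubly positive genes, double trim by rank, inverse
## delta-method weights, weighted mean of M. Independent of tmm_factors().
oracle_tmm_pair <- function(yk, yr, trim_m = 0.30, trim_a = 0.05) {
  Nk <- sum(yk); Nr <- sum(yr)
  keep <- yk > 0 & yr > 0
  yk <- yk[keep]; yr <- yr[keep]
  M <- log2((yk / Nk) / (yr / Nr))
  A <- 0.5 * log2((yk / Nk) * (yr / Nr))
  w <- 1 / ((Nk - yk) / (Nk * yk) + (Nr - yr) / (Nr * yr))
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2 ^ (sum(w[sel] * M[sel]) / sum(w[sel]))
}

## Double-loop BH definition: q_i = min over j with p_j >= p_i ... computed
## directly as min_{j: rank>=rank_i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ri <- which(o == i)  # rank of p_i
    cand <- Inf
    for (j in ri:m) cand <- min(cand, p[o[j]] * m / j)
    q[i] <- min(1, cand)
  }
  q
}

## Per-pair biweight midcorrelation transcription (no outlier capping when
## cap = FALSE tails stay inside; mirrors the documented weight formula).
oracle_bicor_pair <- function(x, y, max_p_outliers = 0.1) {
  prep <- function(v) {
    med <- median(v); madv <- median(abs(v - med))
    u <- (v - med) / (9 * madv)
    ql <- quantile(v, max_p_outliers, names = FALSE)
    qu <- quantile(v, 1 - max_p_outliers, names = FALSE)
    ul <- (ql - med) / (9 * madv); uu <- (qu - med) / (9 * madv)
    if (ul < -1) u[v < med] <- u[v < med] / abs(ul)
    if (uu > 1) u[v > med] <- u[v > med] / uu
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - med) * w
  }
  a <- prep(x); b <- prep(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

## Exact NNLS by enumeration of active sets (<= 3 types): solve the
## unconstrained least squares on every subset of columns, keep feasible
## solutions, return the best.
oracle_nnls <- function(S, b) {
  p <- ncol(S)
  best <- NULL; best_rss <- Inf
  subsets <- unlist(lapply(0:p, function(k)
    combn(p, k, simplify = FALSE)), recursive = FALSE)
  for (s in subsets) {
    x <- rep(0, p)
    if (length(s) > 0) {
      fit <- tryCatch(qr.solve(S[, s, drop = FALSE], b),
                      error = function(e) NULL)
      if (is.null(fit) || any(fit < 0)) next
      x[s] <- fit
    }
    rss <- sum((S %*% x - b)^2)
    if (rss < best_rss - 1e-12) { best_rss <- rss; best <- x }
  }
  best
}
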