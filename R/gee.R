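#' Method-of-moments negative binomial dispersion
#'
#' Estimates the dispersion \eqn{\alpha} of the variance model
#' \eqn{v(\mu) = \mu + \alpha \mu^2} by
#' \eqn{\hat\alpha = \max\!\left(0, \frac{\sum_i (y_i-\mu_i)^2 - \mu_i}
#' {\sum_i \mu_i^2}\right)} so that Poisson-or-under data give 0.
#'
#' @param y observed counts.
#' @param mu fitted means, all positive.
#' @return nonnegative scalar dispersion.
#' @export
estimate_dispersion <- function(y, mu) {
  if (any(mu <= 0)) stop("fitted means must be positive")
  max(0, sum((y - mu)^2 - mu) / sum(mu^2))
}

#' Fit a negative binomial GEE with log link
#'
#' Solves the estimating equations
#' \eqn{\sum_i D_i^\top V_i^{-1} (y_i - \mu_i) = 0} with
#' \eqn{\mu = \exp(X\beta + \mathrm{offset})}, variance function
#' \eqn{v(\mu) = \mu + \alpha\mu^2} and working correlation R either the
#' identity ("independence") or exchangeable with moment-estimated
#' parameter. Standard errors come from the robust sandwich
#' \eqn{B^{-1} M B^{-1}} clustered on `cluster_ids`, consistent under
#' working-correlation misspecification.
#'
#' @param y nonnegative response counts.
#' @param design model matrix X (full rank).
#' @param cluster_ids factor-like vector grouping repeated measures by
#'   subject.
#' @param corstr "independence" or "exchangeable".
#' @param alpha NB dispersion; NULL estimates it once, by
#'   [estimate_dispersion()], from an initial independence Poisson fit and
#'   then holds it fixed.
#' @param offset linear-predictor offset (e.g. log effective library size).
#' @param tol convergence tolerance on the max absolute coefficient change.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @return list of class "gee_fit": `coefficients`, `vcov` (sandwich),
#'   `alpha`, `corstr`, `omega` (exchangeable parameter, NA under
#'   independence), `converged`, `iterations`, `fitted`.
#' @export
fit_gee <- function(y, design, cluster_ids, corstr = "independence",
                    alpha = NULL, offset = NULL, tol = 1e-8, max_iter = 100L) {
  corstr <- match.arg(corstr, c("independence", "exchangeable"))
  if (any(y < 0)) stop("y must be nonnegative")
  X <- as.matrix(design)
  n <- length(y); p <- ncol(X)
  if (is.null(offset)) offset <- rep(0, n)
  cl <- as.integer(factor(cluster_ids))
  cl_index <- split(seq_len(n), cl)
  max_size <- max(lengths(cl_index))

  ## initial beta (and alpha if needed) from an independence Poisson fit
  init <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson(),
                                          offset = offset))
  beta <- init$coefficients
  if (anyNA(beta)) return(failed_gee_fit(X, corstr))
  if (is.null(alpha))
    alpha <- estimate_dispersion(y, pmax(init$fitted.values, 1e-8))

  omega <- 0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(pmin(eta, 30))
    v <- mu + alpha * mu^2
    r_std <- (y - mu) / sqrt(v)
    if (corstr == "exchangeable") {
      num <- 0; n_pairs <- 0
      for (idx in cl_index) {
        m <- length(idx)
        if (m < 2) next
        s <- sum(r_std[idx])
        num <- num + (s^2 - sum(r_std[idx]^2)) / 2
        n_pairs <- n_pairs + m * (m - 1) / 2
      }
      phi_scale <- sum(r_std^2) / max(n - p, 1)
      omega <- if (n_pairs > p) num / ((n_pairs - p) * phi_scale) else 0
      omega <- min(max(omega, -1 / max(max_size - 1, 1) + 1e-6), 0.99)
    }
    B <- matrix(0, p, p)
    score <- numeric(p)
    for (idx in cl_index) {
      m <- length(idx)
      D <- mu[idx] * X[idx, , drop = FALSE]
      a_half <- sqrt(v[idx])
      R <- if (corstr == "independence" || m == 1) diag(m) else
        (1 - omega) * diag(m) + omega
      V <- (a_half %o% a_half) * R
      Vi_D <- solve(V, D)
      B <- B + crossprod(D, Vi_D)
      score <- score + crossprod(Vi_D, y[idx] - mu[idx])
    }
    delta <- tryCatch(solve(B, score), error = function(e) NULL)
    if (is.null(delta)) return(failed_gee_fit(X, corstr, beta, alpha))
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }

  ## sandwich at the final iterate
  eta <- drop(X %*% beta) + offset
  mu <- exp(pmin(eta, 30))
  v <- mu + alpha * mu^2
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (idx in cl_index) {
    m <- length(idx)
    D <- mu[idx] * X[idx, , drop = FALSE]
    a_half <- sqrt(v[idx])
    R <- if (corstr == "independence" || m == 1) diag(m) else
      (1 - omega) * diag(m) + omega
    V <- (a_half %o% a_half) * R
    Vi_D <- solve(V, D)
    B <- B + crossprod(D, Vi_D)
    u <- crossprod(Vi_D, y[idx] - mu[idx])
    M <- M + tcrossprod(u)
  }
  Binv <- tryCatch(solve(B), error = function(e) NULL)
  if (is.null(Binv)) return(failed_gee_fit(X, corstr, beta, alpha))
  vc <- Binv %*% M %*% Binv
  vc <- (vc + t(vc)) / 2
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 vcov = vc, alpha = alpha, corstr = corstr,
                 omega = if (corstr == "exchangeable") omega else NA_real_,
                 converged = converged, iterations = iter, fitted = mu),
            class = "gee_fit")
}

failed_gee_fit <- function(X, corstr, beta = NULL, alpha = NA_real_) {
  p <- ncol(X)
  structure(list(coefficients = stats::setNames(
                   beta %||% rep(NA_real_, p), colnames(X)),
                 vcov = matrix(NA_real_, p, p), alpha = alpha,
                 corstr = corstr, omega = NA_real_, converged = FALSE,
                 iterations = 0L, fitted = NULL),
            class = "gee_fit")
}

#' Joint Wald test on a coefficient subset
#'
#' \eqn{W = \beta_s^\top C_s^{-1} \beta_s} against a chi-square with
#' `length(idx)` degrees of freedom, using the fit's sandwich covariance.
#'
#' @param fit a "gee_fit".
#' @param idx integer positions of the coefficients tested jointly.
#' @return list `W`, `df`, `p` (`p` is NA when the fit did not converge or
#'   the covariance submatrix is singular).
#' @export
wald_joint_test <- function(fit, idx) {
  df <- length(idx)
  bad <- list(W = NA_real_, df = df, p = NA_real_)
  if (!fit$converged) return(bad)
  b <- fit$coefficients[idx]
  C <- fit$vcov[idx, idx, drop = FALSE]
  if (anyNA(b) || anyNA(C)) return(bad)
  Ci <- tryCatch(solve(C), error = function(e) NULL)
  if (is.null(Ci)) return(bad)
  W <- drop(t(b) %*% Ci %*% b)
  list(W = W, df = df, p = stats::pchisq(W, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at
#' 1 and mapped back to input order. Missing p-values are propagated and not
#' counted in m.
#'
#' @param pvalues numeric vector in `[0, 1]` (NA allowed).
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  q <- rep(NA_real_, length(pvalues))
  if (m > 0) {
    o <- order(p)
    qs <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    qo <- numeric(m); qo[o] <- qs
    q[ok] <- qo
  }
  q
}

#' Per-gene longitudinal GEE screen
#'
#' Fits, for every gene, a log-link NB-variance GEE of counts on the
#' timepoint factor (reference `ref`) plus age (and optionally parity and
#' proportion-PC covariates), with offset `log(N_k f_k)` so that integer
#' counts stay the response while effectively modeling normalized
#' expression. Significance of the timepoint profile is a joint sandwich
#' Wald test over all non-reference timepoint indicators, BH-corrected
#' across genes; per-timepoint log2 fold changes vs `ref` are the timepoint
#' coefficients divided by log 2.
#'
#' @param counts filtered genes x samples count matrix.
#' @param factors [tmm_factors()] result on the same samples.
#' @param metadata data.frame with sample_id, subject_id, timepoint, age and
#'   optionally parity, covering all samples.
#' @param pcs optional samples x PCs score matrix (e.g. selected columns of
#'   [proportion_pcs()] scores); its presence labels the variant "adjusted".
#' @param corstr working correlation, "independence" or "exchangeable".
#' @param include_parity add parity as a covariate.
#' @param ref reference timepoint for the factor (default "T0"; use "T3" for
#'   postpartum-vs-late-pregnancy contrasts).
#' @return data.frame, one row per gene: gene, variant, W, df, p, q,
#'   `log2FC_<tp>` for each non-reference timepoint, alpha, converged.
#'   Non-converged genes have NA p and are excluded from the BH correction.
#' @export
run_screen <- function(counts, factors, metadata, pcs = NULL,
                       corstr = "independence", include_parity = FALSE,
                       ref = "T0") {
  md <- metadata[match(colnames(counts), metadata$sample_id), ]
  if (anyNA(md$sample_id)) stop("metadata does not cover all samples")
  tps <- intersect(TIMEPOINT_LEVELS, unique(md$timepoint))
  tp <- factor(md$timepoint, levels = c(ref, setdiff(tps, ref)))
  fml_terms <- c("tp", "age")
  dat <- data.frame(tp = tp, age = md$age)
  if (include_parity) dat$parity <- md$parity
  if (include_parity) fml_terms <- c(fml_terms, "parity")
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (!identical(rownames(pcs), colnames(counts)))
      stop("PC covariates do not match the samples of counts")
    colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
    dat <- cbind(dat, pcs)
    fml_terms <- c(fml_terms, colnames(pcs))
  }
  X <- stats::model.matrix(stats::reformulate(fml_terms), dat)
  tp_idx <- grep("^tp", colnames(X))
  tp_names <- sub("^tp", "", colnames(X)[tp_idx])
  offset <- log(factors$lib_sizes * factors$factors)[colnames(counts)]
  cluster <- md$subject_id

  n_g <- nrow(counts)
  W <- p <- rep(NA_real_, n_g)
  alpha <- rep(NA_real_, n_g)
  converged <- logical(n_g)
  lfc <- matrix(NA_real_, n_g, length(tp_idx),
                dimnames = list(rownames(counts),
                                paste0("log2FC_", tp_names)))
  for (g in seq_len(n_g)) {
    fit <- fit_gee(counts[g, ], X, cluster, corstr = corstr, offset = offset)
    converged[g] <- fit$converged
    alpha[g] <- fit$alpha
    if (!fit$converged) next
    wt <- wald_joint_test(fit, tp_idx)
    W[g] <- wt$W; p[g] <- wt$p
    lfc[g, ] <- fit$coefficients[tp_idx] / log(2)
  }
  n_failed <- sum(!converged)
  if (n_failed > 0)
    message(n_failed, " gene(s) failed GEE convergence; excluded from FDR")
  out <- data.frame(gene = rownames(counts),
                    variant = if (is.null(pcs)) "unadjusted" else "adjusted",
                    W = W, df = length(tp_idx), p = p, q = bh_fdr(p),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(lfc))
  out$alpha <- alpha
  out$converged <- converged
  rownames(out) <- NULL
  out
}
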