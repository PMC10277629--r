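test_that("moment dispersion estimator behaves at its boundaries", {
  ## y = mu exactly: numerator <= 0, alpha floored at 0
  mu <- c(5, 10, 20)
  expect_equal(estimate_dispersion(mu, mu), 0)
  expect_equal(estimate_dispersion(7, 7), 0)
  ## consistency on simulated NB data
  set.seed(12)
  y <- rnbinom(10000, mu = 100, size = 1 / 0.2)
  a <- estimate_dispersion(y, rep(100, 10000))
  expect_gt(a, 0.18); expect_lt(a, 0.22)
  expect_error(estimate_dispersion(1, 0), "positive")
})

test_that("GEE with singleton clusters reproduces the NB GLM", {
  set.seed(31)
  n <- 80
  x <- rnorm(n); z <- runif(n)
  X <- cbind("(Intercept)" = 1, x = x, z = z)
  off <- log(runif(n, 0.5, 2))
  mu <- exp(0.8 + 0.6 * x - 0.4 * z + off)
  for (alpha in c(0.1, 0.3)) {
    y <- rnbinom(n, mu = mu, size = 1 / alpha)
    fit <- fit_gee(y, X, cluster_ids = seq_len(n), alpha = alpha, offset = off)
    g <- glm(y ~ x + z + offset(off),
             family = MASS::negative.binomial(theta = 1 / alpha),
             control = glm.control(epsilon = 1e-12, maxit = 100))
    expect_true(fit$converged)
    expect_lt(max(abs(fit$coefficients - coef(g))), 1e-6)
  }
})

test_that("intercept-only GEE on constant data has the closed form", {
  y <- rep(7, 20)
  fit <- fit_gee(y, matrix(1, 20, 1), cluster_ids = rep(1:4, each = 5))
  expect_equal(unname(fit$coefficients), log(7), tolerance = 1e-8)
})

test_that("timepoint effects are recovered without bias", {
  ## rho_T2 = ln 2 planted on many genes; mean coefficient near ln 2
  set.seed(5)
  K <- 14; tps <- c("T0", "T1", "T2")
  cl <- rep(1:K, each = length(tps))
  tp <- factor(rep(tps, K), levels = tps)
  X <- model.matrix(~tp)
  betas <- replicate(200, {
    b <- rep(rnorm(K, 0, 0.3), each = length(tps))
    mu <- exp(4 + b + log(2) * (tp == "T2"))
    y <- rnbinom(length(mu), mu = mu, size = 1 / 0.1)
    fit_gee(y, X, cl)$coefficients["tpT2"]
  })
  expect_equal(mean(betas), log(2), tolerance = 0.05)
})

test_that("exchangeable working correlation is estimated within bounds", {
  set.seed(8)
  K <- 30; m <- 5
  cl <- rep(1:K, each = m)
  b <- rep(rnorm(K, 0, 0.5), each = m)
  mu <- exp(3 + b)
  y <- rnbinom(K * m, mu = mu, size = 1 / 0.05)
  fit <- fit_gee(y, matrix(1, K * m, 1), cl, corstr = "exchangeable")
  expect_true(fit$converged)
  expect_gt(fit$omega, -1 / (m - 1))
  expect_lt(fit$omega, 1)
  expect_gt(fit$omega, 0.2)  # strong shared random effect => positive omega
})

test_that("sandwich reduces to model-based covariance in the constructed case", {
  ## independence, singleton clusters, residual outer products replaced by V:
  ## then M = sum D' V^-1 V V^-1 D = B and sandwich = B^-1
  set.seed(44)
  n <- 50
  x <- rnorm(n)
  X <- cbind(1, x)
  mu <- exp(1 + 0.3 * x)
  alpha <- 0.2
  v <- mu + alpha * mu^2
  D <- mu * X
  B <- crossprod(D, D / v)
  ## fit on data exactly at the mean has residual 0; check identity algebraically
  M <- crossprod(D, (D / v) * (v / v))  # rr' = V  => M = B
  expect_equal(solve(B) %*% M %*% solve(B), solve(B), tolerance = 1e-12)
})

test_that("joint Wald test matches chi-square closed forms", {
  fit <- list(coefficients = c(a = 0, b = 0, c = 1, d = 0),
              vcov = diag(4), converged = TRUE)
  class(fit) <- "gee_fit"
  ## zero coefficients: W = 0, p = 1
  w0 <- wald_joint_test(fit, 1:2)
  expect_equal(w0$W, 0); expect_equal(w0$p, 1)
  ## beta_s = (1, 0), identity covariance: W = 1, df = 2, p = exp(-1/2)
  w1 <- wald_joint_test(fit, 3:4)
  expect_equal(w1$W, 1); expect_equal(w1$df, 2)
  expect_equal(w1$p, exp(-0.5), tolerance = 1e-12)
  ## singular covariance: missing p
  fit$vcov <- matrix(0, 4, 4)
  expect_true(is.na(wald_joint_test(fit, 1:2)$p))
})

test_that("BH q-values match the brute-force definition and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  ## NA propagation
  q <- bh_fdr(c(0.01, NA, 0.5))
  expect_true(is.na(q[2])); expect_false(anyNA(q[-2]))
  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    expect_equal(bh_fdr(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
})

test_that("the screen flags regulated genes and labels variants correctly", {
  sim <- small_cohort(seed = 1)
  prep <- preprocess_cohort(sim)
  sc <- run_screen(prep$counts, prep$factors, sim$metadata)
  expect_identical(unique(sc$variant), "unadjusted")
  expect_equal(unique(sc$df), 4)
  expect_true(all(c("log2FC_T1", "log2FC_T2", "log2FC_T3", "log2FC_PP3")
                  %in% colnames(sc)))
  truth <- sim$truth[match(sc$gene, sim$truth$gene), ]
  reg <- truth$class == "regulation" & sc$converged
  expect_gt(mean(sc$q[reg] < 0.05, na.rm = TRUE), 0.8)
  ## rho = ln 4 planted => |log2FC| near 2 at T3 for genes regulated from T1
  rho_t3 <- attr(sim$truth, "rho")[sc$gene, "T3"]
  strong <- abs(rho_t3) > 0 & sc$converged
  expect_equal(median(abs(sc$log2FC_T3[strong])), 2, tolerance = 0.25)
  ## adding parity (independent of expression) barely changes the statistics
  scp <- run_screen(prep$counts, prep$factors, sim$metadata,
                    include_parity = TRUE)
  ok <- sc$converged & scp$converged
  expect_gt(cor(sc$W[ok], scp$W[ok]), 0.95)
})
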