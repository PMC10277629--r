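planted_blocks <- function(n_per_block = 60, n_samples = 40, within = 0.8,
                           seed = 5, n_blocks = 2) {
  set.seed(seed)
  expr <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    shared <- rnorm(n_samples)
    t(sapply(seq_len(n_per_block), function(i)
      sqrt(within) * shared + sqrt(1 - within) * rnorm(n_samples)))
  }))
  dimnames(expr) <- list(sprintf("g%03d", seq_len(nrow(expr))),
                         sprintf("s%02d", seq_len(n_samples)))
  expr
}

test_that("bicor equals the per-pair weight-formula transcription", {
  set.seed(41)
  expr <- matrix(rnorm(12 * 30), 12, 30,
                 dimnames = list(paste0("g", 1:12), paste0("s", 1:30)))
  expr[3, 7] <- 8  # one gross outlier
  C <- bicor_matrix(expr)
  for (i in 1:11) for (j in (i + 1):12) {
    expect_equal(C[i, j], oracle_bicor_pair(expr[i, ], expr[j, ]),
                 tolerance = 1e-12)
  }
  ## self and anti-self
  expect_equal(unname(diag(C)), rep(1, 12))
  x <- expr[1, ]
  C2 <- bicor_matrix(rbind(a = x, b = -x, c = expr[2, ], d = expr[3, ]))
  expect_equal(C2["a", "b"], -1, tolerance = 1e-12)
})

test_that("bicor resists a gross outlier better than Pearson", {
  set.seed(6)
  n <- 20
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(n)
  true_cor <- cor(x[-n], y[-n])
  x_out <- x; y_out <- y
  x_out[n] <- 10; y_out[n] <- -10
  C <- bicor_matrix(rbind(a = x_out, b = y_out, c = rnorm(n), d = rnorm(n)))
  expect_lt(abs(C["a", "b"] - true_cor), abs(cor(x_out, y_out) - true_cor))
})

test_that("bicor equals Pearson when no sample is down-weighted", {
  ## symmetric, tightly clustered data: all |u| < 1 and weights ~ shape only
  set.seed(2)
  expr <- matrix(rnorm(6 * 200), 6, 200,
                 dimnames = list(paste0("g", 1:6), NULL))
  colnames(expr) <- paste0("s", seq_len(ncol(expr)))
  C <- bicor_matrix(expr)
  P <- cor(t(expr))
  expect_equal(C, P, tolerance = 0.05)  # Gaussian: bicor ~ Pearson
  ## constant gene: Pearson fallback with message, correlation 0
  expr2 <- rbind(expr, const = rep(1, ncol(expr)))
  expect_message(C2 <- bicor_matrix(expr2), "MAD")
  expect_true(all(abs(C2["const", setdiff(rownames(expr2), "const")]) < 1e-12))
  expect_error(bicor_matrix(expr[, 1:3]), "4 samples")
})

test_that("signed-hybrid adjacency zeroes negatives and powers positives", {
  C <- matrix(c(1, 0.8, -0.5, 0.8, 1, 0.3, -0.5, 0.3, 1), 3, 3)
  A <- adjacency_signed_hybrid(C, beta = 5)
  expect_equal(A[1, 2], 0.8^5)
  expect_equal(A[1, 3], 0)
  expect_equal(unname(diag(A)), rep(1, 3))
  expect_error(adjacency_signed_hybrid(C, beta = 0), "beta")
  expect_error(adjacency_signed_hybrid(C * 2), "\\[-1, 1\\]")
})

test_that("TOM matches hand evaluation and stays within bounds", {
  ## complete triangle: TOM_12 = (a13 a32 + a12)/(min(k1,k2) + 1 - a12) = 1
  A <- matrix(1, 3, 3)
  expect_equal(tom_similarity(A)[1, 2], 1)
  ## disconnected pair with no shared neighbors
  A2 <- diag(4)
  A2[1, 2] <- A2[2, 1] <- 0
  A2[3, 4] <- A2[4, 3] <- 0.5
  expect_equal(tom_similarity(A2)[1, 2], 0)
  ## hand-computed asymmetric-degree case
  A3 <- diag(3)
  A3[1, 2] <- A3[2, 1] <- 0.6
  A3[1, 3] <- A3[3, 1] <- 0.4
  A3[2, 3] <- A3[3, 2] <- 0.2
  t12 <- (0.4 * 0.2 + 0.6) / (min(1.0, 0.8) + 1 - 0.6)
  expect_equal(tom_similarity(A3)[1, 2], t12, tolerance = 1e-12)
  ## property: symmetric, in [0, 1], on random valid adjacencies
  set.seed(19)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    R <- matrix(runif(n * n), n)
    A <- (R + t(R)) / 2; diag(A) <- 1
    tom <- tom_similarity(A)
    expect_true(isSymmetric(tom, tol = 1e-10))
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
  }
  expect_error(tom_similarity(matrix(runif(9), 3)), "symmetric")
})

test_that("planted blocks are recovered through the full module pipeline", {
  expr <- planted_blocks()
  ma <- coexpression_modules(expr)
  labels <- ma$labels
  expect_equal(length(setdiff(unique(labels), "grey")), 2)
  truth <- rep(1:2, each = 60)
  expect_gt(rand_index(truth, as.integer(factor(labels))), 0.95)
  ## eigengene invariants: unit norm, post-merge separation
  expect_true(all(abs(sqrt(colSums(ma$eigengenes^2)) - 1) < 1e-9))
  if (ncol(ma$eigengenes) > 1) {
    eg_cor <- cor(ma$eigengenes)
    expect_true(all(eg_cor[upper.tri(eg_cor)] < 1 - ma$merge_cut))
  }
})

test_that("uncorrelated genes form no module; identical profiles merge to one", {
  set.seed(9)
  expr0 <- matrix(rnorm(50 * 40), 50, 40,
                  dimnames = list(paste0("g", 1:50), paste0("s", 1:40)))
  suppressWarnings(ma0 <- coexpression_modules(expr0, min_module_size = 30))
  expect_true(all(ma0$labels == "grey"))
  ## two detected blocks with identical underlying profile are merged
  set.seed(10)
  shared <- rnorm(40)
  expr1 <- t(sapply(1:70, function(i) sqrt(0.9) * shared + sqrt(0.1) * rnorm(40)))
  dimnames(expr1) <- list(paste0("g", 1:70), paste0("s", 1:40))
  labels <- setNames(rep(c("blue", "turquoise"), times = c(35, 35)),
                     rownames(expr1))
  merged <- merge_modules(expr1, labels, merge_cut = 0.25)
  expect_equal(length(setdiff(unique(merged$labels), "grey")), 1)
  expect_gt(merged$merges, 0)
  ## dissimilar modules are not merged
  expr2 <- planted_blocks(within = 0.9, seed = 12)
  labels2 <- setNames(rep(c("blue", "turquoise"), each = 60), rownames(expr2))
  merged2 <- merge_modules(expr2, labels2, merge_cut = 0.25)
  expect_equal(length(setdiff(unique(merged2$labels), "grey")), 2)
})

test_that("module labels are deterministic and size-ordered", {
  expr <- planted_blocks(n_per_block = 45, seed = 14)
  extra <- planted_blocks(n_per_block = 70, seed = 15)[1:70, ]
  rownames(extra) <- sprintf("h%03d", 1:70)
  all_expr <- rbind(expr[1:45, ], extra)  # one block of 45, one of 70
  ma1 <- coexpression_modules(all_expr)
  ma2 <- coexpression_modules(all_expr)
  expect_identical(ma1$labels, ma2$labels)
  sizes <- table(ma1$labels[ma1$labels != "grey"])
  ## largest module gets the first palette color
  expect_identical(names(which.max(sizes)), "turquoise")
})
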