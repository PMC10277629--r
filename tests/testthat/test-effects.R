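fake_screen <- function(q, l1, l2, l3, genes = NULL) {
  n <- length(q)
  data.frame(gene = genes %||% paste0("g", seq_len(n)),
             variant = "unadjusted", W = 10, df = 3, p = q, q = q,
             log2FC_T1 = l1, log2FC_T2 = l2, log2FC_T3 = l3,
             converged = TRUE, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pregnancy-associated calling applies the dual FDR/FC rule", {
  sc <- fake_screen(q = c(0.01, 0.2, 0.01, 0.01),
                    l1 = c(0.5, 3, 0.2, 1.0),
                    l2 = c(1.2, 3, 0.3, 0.5),
                    l3 = c(1.5, 3, 0.4, -0.2))
  calls <- call_pregnancy_associated(sc)
  ## flagged iff q < 0.05 and max |log2FC| >= 1
  expect_identical(calls$flagged, c(TRUE, FALSE, FALSE, TRUE))
  ## per-timepoint flags for gene 1: (F, T, T)
  expect_identical(unlist(calls[1, c("flag_T1", "flag_T2", "flag_T3")],
                          use.names = FALSE), c(FALSE, TRUE, TRUE))
  ## boundary |log2FC| = 1 passes (gene 4 at T1)
  expect_true(calls$flag_T1[4])
  ## monotonicity: stricter thresholds never add genes
  calls_strict <- call_pregnancy_associated(sc, fdr = 0.01, fc = 4)
  expect_true(all(calls$flagged | !calls_strict$flagged))
  calls_fc1 <- call_pregnancy_associated(sc, fc = 1)
  expect_true(all(calls_fc1$flagged | !calls$flagged))
  expect_gte(sum(calls_fc1$flagged), sum(calls$flagged))
  expect_error(call_pregnancy_associated(sc, timepoints = "PP9"), "lacks")
})

test_that("onset is the earliest flagged trimester and appending PP timepoints is stable", {
  f <- rbind(c(FALSE, TRUE, TRUE),
             c(TRUE, FALSE, FALSE),
             c(FALSE, FALSE, FALSE))
  colnames(f) <- paste0("flag_", c("T1", "T2", "T3"))
  expect_identical(onset_timepoint(f), c("T2", "T1", NA))
  f2 <- cbind(f, flag_PP3 = c(TRUE, TRUE, FALSE))
  expect_identical(onset_timepoint(f2)[1:2], c("T2", "T1"))
})

test_that("mechanism classes partition the gene universe by the set algebra", {
  un <- data.frame(gene = paste0("g", 1:4),
                   flagged = c(TRUE, TRUE, FALSE, FALSE),
                   flag_T1 = c(TRUE, FALSE, FALSE, FALSE),
                   flag_T2 = c(TRUE, TRUE, FALSE, FALSE),
                   flag_T3 = c(FALSE, TRUE, FALSE, FALSE))
  ad <- data.frame(gene = paste0("g", c(2, 1, 3, 4)),   # scrambled order
                   flagged = c(TRUE, FALSE, TRUE, FALSE),
                   flag_T1 = c(FALSE, FALSE, TRUE, FALSE),
                   flag_T2 = c(TRUE, FALSE, FALSE, FALSE),
                   flag_T3 = c(TRUE, FALSE, TRUE, FALSE))
  mech <- classify_mechanism(un, ad)
  expect_identical(mech$class, c("composition", "mixed", "regulation", "none"))
  ## a partition: one class per gene, all genes covered
  expect_identical(sort(mech$gene), sort(un$gene))
  expect_true(all(mech$class %in% c("none", "composition", "mixed", "regulation")))
  ## onset source: unadjusted for composition/mixed, adjusted for regulation
  expect_identical(mech$onset, c("T1", "T2", "T1", NA))
  ## universe mismatch is rejected with the offending ids
  expect_error(classify_mechanism(un, ad[1:3, ]), "g4")
})

test_that("venn counts tabulate flag patterns of flagged genes only", {
  un <- data.frame(gene = paste0("g", 1:5),
                   flagged = c(TRUE, TRUE, TRUE, FALSE, TRUE),
                   flag_T1 = c(TRUE, FALSE, TRUE, TRUE, FALSE),
                   flag_T2 = c(TRUE, TRUE, FALSE, TRUE, FALSE),
                   flag_T3 = c(FALSE, TRUE, FALSE, TRUE, TRUE))
  v <- onset_venn_counts(un)
  expect_identical(v$n[match("T1+T2", v$pattern)], 1L)
  expect_identical(v$n[match("T3", v$pattern)], 1L)
  expect_false("T1+T2+T3" %in% v$pattern)  # gene 4 not flagged
  expect_equal(sum(v$n), 4)
})

test_that("reversion correlation hits -1 on exact reversion and guards small subsets", {
  ## construct screens where PP3-vs-T3 change is exactly minus the T0->T3 change
  n <- 20
  l3 <- seq(-3, 3, length.out = n)
  t0 <- fake_screen(q = rep(0.001, n), l1 = 0, l2 = 0, l3 = l3)
  t3 <- data.frame(gene = t0$gene, variant = "unadjusted", W = 10, df = 3,
                   p = 0.001, q = 0.001, log2FC_PP3 = -l3,
                   converged = TRUE, stringsAsFactors = FALSE)
  rev <- reversion_correlation(t0, t3)
  expect_equal(rev$r, -1, tolerance = 1e-12)
  ## only genes passing the PP3 gate (|log2FC_PP3| >= 1, q < 0.05) are used
  expect_equal(rev$n, sum(abs(l3) >= 1))
  ## fewer than 3 qualifying genes: missing with warning
  t3_few <- t3; t3_few$q <- c(0.001, 0.001, rep(0.9, n - 2))
  expect_warning(r2 <- reversion_correlation(t0, t3_few), "fewer than 3")
  expect_true(is.na(r2$r))
})

test_that("mechanism recovery scores planted cohorts sensibly", {
  truth <- data.frame(gene = paste0("g", 1:6),
                      class = c("null", "null", "composition",
                                "regulation", "regulation", "mixed"))
  mech <- data.frame(gene = paste0("g", 1:6),
                     class = c("none", "none", "composition",
                               "mixed", "regulation", "mixed"))
  rec <- mechanism_recovery(truth, mech)
  ## regulation scored as recovered for both "regulation" and "mixed" labels
  expect_equal(rec$per_class_recall[["regulation"]], 1)
  expect_equal(rec$per_class_recall[["null"]], 1)
  expect_equal(rec$balanced_accuracy, 1)
  ## a composition gene called mixed is a miss
  mech$class[3] <- "mixed"
  rec2 <- mechanism_recovery(truth, mech)
  expect_equal(rec2$per_class_recall[["composition"]], 0)
})
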