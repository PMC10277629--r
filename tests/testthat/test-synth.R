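test_that("signature generation enforces marker structure and determinism", {
  sig <- generate_signature(8, 2, markers_per_type = 2, marker_fold = 10, seed = 1)
  expect_equal(dim(sig), c(8, 2))
  mt <- marker_types(sig)
  for (ct in colnames(sig)) {
    m <- names(mt)[!is.na(mt) & mt == ct]
    expect_length(m, 2)
    other <- setdiff(colnames(sig), ct)
    expect_true(all(sig[m, ct] >= 10 * apply(sig[m, other, drop = FALSE], 1, max)))
  }
  expect_true(all(sig > 0))
  expect_identical(sig, generate_signature(8, 2, 2, 10, seed = 1))
  expect_false(identical(sig, generate_signature(8, 2, 2, 10, seed = 2)))
  expect_error(generate_signature(3, 2, markers_per_type = 2), "n_genes")
  expect_error(generate_signature(8, 2, 2, marker_fold = 0.5), "marker_fold")
  expect_error(generate_signature(-1, 2, 2), "positive")
})

test_that("composition trajectories live on the simplex and respect shifts", {
  alpha <- setNames(c(5, 3, 2), c("neutrophil", "tcell", "bcell"))
  tps <- c("T0", "T1", "T2")
  ## no shift: identical to baseline at every timepoint
  comps0 <- generate_compositions(10, tps, alpha, seed = 3)
  for (t in tps) expect_equal(comps0[, t, ], comps0[, "T0", ], tolerance = 1e-12)
  expect_equal(apply(comps0, c(1, 2), sum), matrix(1, 10, 3,
               dimnames = dimnames(comps0)[1:2]), tolerance = 1e-9)
  ## positive shift raises the shifted type's median proportion
  sh <- matrix(0, 3, 3, dimnames = list(tps, names(alpha)))
  sh[c("T1", "T2"), "neutrophil"] <- 0.8
  comps <- generate_compositions(200, tps, alpha, sh, seed = 4)
  expect_gt(median(comps[, "T2", "neutrophil"]), median(comps[, "T0", "neutrophil"]))
  expect_identical(attr(comps, "shifted_types"), "neutrophil")
  ## cohort-shaped call
  c14 <- generate_compositions(14, c("T0", "T1", "T2", "T3", "PP3"), alpha, seed = 5)
  expect_equal(dim(c14), c(14, 5, 3))
  expect_true(all(abs(apply(c14, c(1, 2), sum) - 1) < 1e-9))
  expect_error(generate_compositions(5, tps, c(1, -1, 1)), "alpha")
  expect_error(generate_compositions(5, c("T0", "XX"), alpha), "timepoint")
})

test_that("count generator matches its closed-form mean", {
  ## tau = 0, rho = 0, constant composition, tiny dispersion: empirical mean
  ## of each gene across replicate samples approximates mu within 3 SE
  sig <- generate_signature(30, 2, markers_per_type = 3, marker_fold = 10, seed = 6)
  alpha <- setNames(c(5, 5), colnames(sig))
  n_rep <- 500
  comps <- generate_compositions(n_rep, "T0", alpha, seed = 7)
  comps[] <- rep(rep(c(0.4, 0.6), each = n_rep), 1)  # fix composition exactly
  plan <- default_regulation_plan(sig, "T0", frac_regulated = 0, tau = 0,
                                  phi_range = c(0.01, 0.010001),
                                  lib_size_sdlog = 0, seed = 8)
  sim <- generate_counts(sig, comps, plan, seed = 9)
  mix <- sig %*% c(0.4, 0.6)
  mu <- exp(plan$lib_size_meanlog) * mix / sum(mix)
  emp <- rowMeans(sim$counts)
  se <- sqrt((mu + 0.01 * mu^2) / n_rep)
  expect_true(all(abs(emp - mu) < 3.5 * se))
})

test_that("planted regulation shows up as the planted fold change", {
  sig <- generate_signature(40, 2, markers_per_type = 3, marker_fold = 10, seed = 10)
  alpha <- setNames(c(5, 5), colnames(sig))
  comps <- generate_compositions(300, c("T0", "T2"), alpha, seed = 11)
  plan <- default_regulation_plan(sig, c("T0", "T2"), frac_regulated = 0,
                                  tau = 0, phi_range = c(0.01, 0.010001),
                                  lib_size_sdlog = 0, seed = 12)
  g <- rownames(sig)[20]
  plan$rho[g, "T2"] <- log(2)
  sim <- generate_counts(sig, comps, plan, seed = 13)
  tp <- sim$metadata$timepoint[match(colnames(sim$counts), sim$metadata$sample_id)]
  ratio <- mean(sim$counts[g, tp == "T2"]) / mean(sim$counts[g, tp == "T0"])
  expect_equal(ratio, 2, tolerance = 0.1)
})

test_that("cohort metadata matches the study design and truth is recomputable", {
  sim <- small_cohort(seed = 1)
  md <- sim$metadata
  expect_setequal(unique(md$timepoint), c("T0", "T1", "T2", "T3", "PP3"))
  expect_equal(length(unique(md$subject_id)), 14)
  expect_true(all(md$age > 18))
  expect_true(all(md$parity %in% 0:2))
  ## ages center near the design mean
  ages <- tapply(md$age, md$subject_id, unique)
  expect_equal(mean(ages), 28.9, tolerance = 1.5)
  ## truth labels recomputable from ingredients
  recomputed <- longidecomp:::recompute_truth_classes(
    sim$signature, sim$compositions, sim$plan)
  expect_identical(unname(recomputed[sim$truth$gene]), sim$truth$class)
  ## class definitions: markers of the shifted type with no rho
  shifted <- attr(sim$compositions, "shifted_types")
  mt <- marker_types(sim$signature)
  comp_genes <- sim$truth$gene[sim$truth$class == "composition"]
  expect_true(all(mt[comp_genes] %in% shifted))
  expect_true(all(rowSums(abs(sim$plan$rho[comp_genes, ])) == 0))
  reg_genes <- sim$truth$gene[sim$truth$class == "regulation"]
  expect_true(all(rowSums(abs(sim$plan$rho[reg_genes, ])) > 0))
  ## determinism of the full generator
  sim2 <- simulate_cohort(n_subjects = 14, n_genes = 400, n_cell_types = 8,
                          markers_per_type = 10, seed = 1)
  expect_identical(sim$counts, sim2$counts)
  expect_identical(sim$metadata, sim2$metadata)
})

test_that("generator rejects inconsistent inputs", {
  sim <- small_cohort(seed = 1)
  bad_plan <- sim$plan
  bad_plan$phi[1] <- -0.1
  expect_error(generate_counts(sim$signature, sim$compositions, bad_plan),
               "phi")
  bad_plan2 <- sim$plan
  bad_plan2$rho[1, "T0"] <- 0.5
  expect_error(generate_counts(sim$signature, sim$compositions, bad_plan2),
               "T0")
  expect_error(generate_counts(sim$signature[-1, ], sim$compositions, sim$plan),
               "gene sets")
})
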