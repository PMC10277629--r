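#!/usr/bin/env Rscript
## Stage 4 — paired longitudinal GEE screens.
##
## Per gene: log-link GEE with NB variance, timepoint factor (T0 reference)
## plus age, offset log(N_k f_k), robust sandwich SEs clustered by subject,
## joint Wald test over the timepoint profile, BH FDR. Run twice: without
## (unadjusted) and with (adjusted) the selected proportion-PC covariates.
## A third screen releveled to T3 supplies the postpartum contrast.

suppressMessages(library(longidecomp))
outdir <- "results/analysis"

counts <- read_counts(file.path(outdir, "filtered_counts.tsv"))
nf <- read.delim(file.path(outdir, "norm_factors.tsv"))
factors <- list(factors = setNames(nf$factor, nf$sample),
                lib_sizes = setNames(nf$lib_size, nf$sample),
                ref_sample = nf$ref[1])
metadata <- read.delim(file.path(outdir, "metadata.tsv"))
pc <- read.delim(file.path(outdir, "pc_scores.tsv"))
scores <- as.matrix(pc[, -1]); rownames(scores) <- pc$sample
sel <- as.integer(readLines(file.path(outdir, "selected_pcs.txt")))

un <- run_screen(counts, factors, metadata)
ad <- run_screen(counts, factors, metadata,
                 pcs = scores[, sel, drop = FALSE])
t3 <- run_screen(counts, factors, metadata, ref = "T3")

write.table(un, file.path(outdir, "screen_unadjusted.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ad, file.path(outdir, "screen_adjusted.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(t3, file.path(outdir, "screen_t3ref.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("genes with q < 0.05 (any fold change): unadjusted ",
        sum(un$q < 0.05, na.rm = TRUE), ", adjusted ",
        sum(ad$q < 0.05, na.rm = TRUE))
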