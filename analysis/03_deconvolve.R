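#!/usr/bin/env Rscript
## Stage 3 — cell-type deconvolution and PC covariates.
##
## Estimates per-sample cell-type proportions by NNLS against the signature,
## tests each type's change vs the T0 baseline (paired Wilcoxon signed-rank),
## condenses the proportions into principal components and keeps the PCs
## associated with gene expression as covariates for the adjusted screen.

suppressMessages(library(longidecomp))
outdir <- "results/analysis"

counts <- read_counts(file.path(outdir, "filtered_counts.tsv"))
nf <- read.delim(file.path(outdir, "norm_factors.tsv"))
factors <- list(factors = setNames(nf$factor, nf$sample),
                lib_sizes = setNames(nf$lib_size, nf$sample),
                ref_sample = nf$ref[1])
metadata <- read.delim(file.path(outdir, "metadata.tsv"))
signature <- read_signature(file.path(outdir, "signature.tsv"))

cpm <- cpm_normalized(counts, factors)
logcpm <- cpm_normalized(counts, factors, log = TRUE)

est <- estimate_proportions(cpm, signature)
write.table(cbind(data.frame(sample = rownames(est$proportions)),
                  as.data.frame(est$proportions)),
            file.path(outdir, "proportions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

tests <- proportion_change_tests(est, metadata)
tests$q <- bh_fdr(tests$p)
write.table(tests, file.path(outdir, "proportion_tests.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
sig_types <- unique(tests$cell_type[tests$q < 0.05])
message("cell types with significant proportion changes vs T0: ",
        if (length(sig_types)) paste(sig_types, collapse = ", ") else "none")

pcs <- proportion_pcs(est)
sel <- select_pcs(pcs, logcpm)
message("proportion PCs: ", pcs$n_pcs, "; selected as covariates: ",
        paste(sel, collapse = ", "))
write.table(cbind(data.frame(sample = rownames(pcs$scores)),
                  as.data.frame(pcs$scores)),
            file.path(outdir, "pc_scores.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(as.character(sel), file.path(outdir, "selected_pcs.txt"))
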