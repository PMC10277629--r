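#!/usr/bin/env Rscript
## Stage 6 — weighted co-expression modules.
##
## bicor (maxPOutliers 0.1) -> signed-hybrid adjacency (power 5) -> TOM ->
## average-linkage clustering with a static cut -> eigengene merging at
## dissimilarity 0.25, over the log-CPM of all analyzed genes.

suppressMessages(library(longidecomp))
outdir <- "results/analysis"

counts <- read_counts(file.path(outdir, "filtered_counts.tsv"))
nf <- read.delim(file.path(outdir, "norm_factors.tsv"))
factors <- list(factors = setNames(nf$factor, nf$sample),
                lib_sizes = setNames(nf$lib_size, nf$sample),
                ref_sample = nf$ref[1])
logcpm <- cpm_normalized(counts, factors, log = TRUE)

ma <- coexpression_modules(logcpm, beta = 5, max_p_outliers = 0.1,
                           min_module_size = 30, cut_height = 0.995,
                           merge_cut = 0.25)
sizes <- sort(table(ma$labels[ma$labels != "grey"]), decreasing = TRUE)
message(length(sizes), " modules (", sum(ma$labels == "grey"),
        " genes unassigned): ",
        paste(names(sizes), sizes, collapse = ", "))

write.table(data.frame(gene = names(ma$labels), module = unname(ma$labels)),
            file.path(outdir, "modules.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(data.frame(sample = rownames(ma$eigengenes)),
                  as.data.frame(ma$eigengenes)),
            file.path(outdir, "eigengenes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
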