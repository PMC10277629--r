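#!/usr/bin/env Rscript
## Stage 2 — gene filtering and TMM normalization.
##
## Drops excluded biotypes, applies the adaptive low-expression rule
## (CPM > 10/L in >= 8 samples, L = smallest library in millions), computes
## trimmed-mean-of-M-values scaling factors and writes the filtered counts
## plus the factor table for the downstream stages.

suppressMessages(library(longidecomp))
outdir <- "results/analysis"

counts <- read_counts(file.path(outdir, "counts.tsv"))
n0 <- nrow(counts)
counts <- filter_gene_types(counts)
counts <- filter_low_expression(counts, cpm_numerator = 10, min_samples = 8)
message("genes: ", n0, " -> ", nrow(counts), " after biotype + expression filters")

factors <- tmm_factors(counts)
message("TMM reference sample: ", factors$ref_sample,
        "; factor range ", round(min(factors$factors), 3), " - ",
        round(max(factors$factors), 3))

write_counts(counts, file.path(outdir, "filtered_counts.tsv"))
write.table(data.frame(sample = names(factors$factors),
                       factor = unname(factors$factors),
                       lib_size = unname(factors$lib_sizes),
                       ref = factors$ref_sample),
            file.path(outdir, "norm_factors.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
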