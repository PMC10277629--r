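#!/usr/bin/env Rscript
## Stage 1 — simulate the reference longitudinal cohort.
##
## 14 subjects sampled before pregnancy (T0), once per trimester (T1-T3) and
## at 3 months postpartum (PP3); 2,000 genes mixed from 8 cell-type
## signatures. One modest-abundance cell type rises during pregnancy
## (log-odds +1 at T1-T3, reverting at PP3) and 10% of non-marker genes
## carry a planted four-fold regulation effect with varying onset, also
## reverting postpartum. Everything downstream treats the written TSVs as
## the "observed" data; the truth table is only used for evaluation.

suppressMessages(library(longidecomp))
outdir <- "results/analysis"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_cohort(seed = 1)

write_signature(sim$signature, file.path(outdir, "signature.tsv"))
write_counts(sim$counts, file.path(outdir, "counts.tsv"))
write.table(sim$metadata, file.path(outdir, "metadata.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth, file.path(outdir, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("cohort: ", nrow(sim$counts), " genes x ", ncol(sim$counts),
        " samples (", length(unique(sim$metadata$subject_id)), " subjects)")
message("truth classes: ",
        paste(names(table(sim$truth$class)), table(sim$truth$class),
              collapse = ", "))
message("mean age at conception: ",
        round(mean(tapply(sim$metadata$age, sim$metadata$subject_id, unique)), 1),
        " years")
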