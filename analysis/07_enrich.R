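#!/usr/bin/env Rscript
## Stage 7 — hypergeometric enrichment.
##
## Tests each co-expression module for over-representation of the genes
## that become pregnancy-associated at each onset trimester, and the full
## flagged list against the cell-type marker sets (written as a GMT and
## read back, exercising the gene-set IO path). Universe = all genes
## surviving the expression filter.

suppressMessages(library(longidecomp))
outdir <- "results/analysis"

mech <- read.delim(file.path(outdir, "mechanism.tsv"))
modules <- read.delim(file.path(outdir, "modules.tsv"))
signature <- read_signature(file.path(outdir, "signature.tsv"))
counts <- read_counts(file.path(outdir, "filtered_counts.tsv"))

assignment <- list(labels = setNames(modules$module, modules$gene))
onsets <- mech$onset
stage_lists <- lapply(setNames(nm = c("T1", "T2", "T3")), function(tp)
  mech$gene[!is.na(onsets) & onsets == tp])

mod_tab <- module_set_enrichment(assignment, stage_lists)
write.table(mod_tab, file.path(outdir, "module_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
hits <- mod_tab[mod_tab$q < 0.05, ]
message("module-stage enrichments at FDR < 0.05: ",
        if (nrow(hits)) paste(hits$stage, hits$set, signif(hits$q, 2),
                              collapse = "; ") else "none")

mt <- marker_types(signature)
marker_sets <- split(names(mt)[!is.na(mt)], mt[!is.na(mt)])
gmt <- file.path(outdir, "marker_sets.gmt")
write_gmt(marker_sets, gmt)
coll <- list(sets = read_gmt(gmt), universe = rownames(counts))
flagged <- mech$gene[mech$class != "none"]
marker_tab <- enrich_collection(flagged, coll)
write.table(marker_tab, file.path(outdir, "marker_enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
top <- marker_tab[1, ]
message("top marker-set enrichment: ", top$set, " (fold ",
        round(top$fold, 1), ", q = ", signif(top$q, 2), ")")
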