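#' Call genes with time-associated expression
#'
#' A gene is flagged iff its screen q-value is below `fdr` AND the largest
#' absolute log2 fold change over the tested contrasts reaches `log2(fc)`
#' (boundary included: |log2FC| = log2(fc) passes). Per-timepoint flags mark
#' the contrasts at which a flagged gene individually reaches the
#' fold-change bar.
#'
#' @param screen a [run_screen()] result.
#' @param fdr q-value threshold.
#' @param fc linear fold-change threshold (2 means |log2FC| >= 1).
#' @param timepoints contrast columns gating the call (default the three
#'   trimesters).
#' @return data.frame gene, flagged, and one `flag_<tp>` column per tested
#'   timepoint.
#' @export
call_pregnancy_associated <- function(screen, fdr = 0.05, fc = 2,
                                      timepoints = c("T1", "T2", "T3")) {
  cols <- paste0("log2FC_", timepoints)
  missing_cols <- setdiff(cols, colnames(screen))
  if (length(missing_cols))
    stop("screen lacks columns: ", paste(missing_cols, collapse = ", "))
  lfc <- abs(as.matrix(screen[, cols, drop = FALSE]))
  thr <- log2(fc)
  max_lfc <- apply(lfc, 1, max)
  flagged <- !is.na(screen$q) & screen$q < fdr &
    !is.na(max_lfc) & max_lfc >= thr
  flags <- lfc >= thr & flagged
  flags[is.na(flags)] <- FALSE
  out <- data.frame(gene = screen$gene, flagged = flagged,
                    stringsAsFactors = FALSE)
  colnames(flags) <- paste0("flag_", timepoints)
  cbind(out, as.data.frame(flags))
}

#' Onset timepoint of an expression change
#'
#' @param flags logical matrix (genes x ordered timepoints) or vector of
#'   per-timepoint flags, e.g. the `flag_*` columns of
#'   [call_pregnancy_associated()].
#' @return character vector: the earliest flagged timepoint per gene, or NA
#'   if none.
#' @export
onset_timepoint <- function(flags) {
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1)
  tp <- sub("^flag_", "", colnames(flags) %||% paste0("t", seq_len(ncol(flags))))
  apply(flags, 1, function(f) {
    i <- which(f)[1]
    if (is.na(i)) NA_character_ else tp[i]
  })
}

#' Classify the mechanism behind each gene's expression change
#'
#' Set algebra over the paired screens: a gene significant only without the
#' cell-proportion adjustment is driven by composition change; only with the
#' adjustment, by transcriptional regulation; in both, by a mixture; in
#' neither, unchanged.
#'
#' @param unadjusted_calls,adjusted_calls [call_pregnancy_associated()]
#'   results on the same gene universe (unadjusted / PC-adjusted screens).
#' @return data.frame gene, class (none/composition/mixed/regulation), onset
#'   (from the unadjusted flags, falling back to adjusted for
#'   regulation-only genes), and the per-timepoint flags of both variants
#'   (prefixed `un_`/`adj_`).
#' @export
classify_mechanism <- function(unadjusted_calls, adjusted_calls) {
  if (!setequal(unadjusted_calls$gene, adjusted_calls$gene)) {
    off <- c(setdiff(unadjusted_calls$gene, adjusted_calls$gene),
             setdiff(adjusted_calls$gene, unadjusted_calls$gene))
    stop("gene universes differ: ", paste(utils::head(off, 10), collapse = ", "))
  }
  adj <- adjusted_calls[match(unadjusted_calls$gene, adjusted_calls$gene), ]
  u <- unadjusted_calls$flagged
  a <- adj$flagged
  cls <- ifelse(u & a, "mixed",
                ifelse(u, "composition",
                       ifelse(a, "regulation", "none")))
  ucols <- grep("^flag_", colnames(unadjusted_calls), value = TRUE)
  acols <- grep("^flag_", colnames(adj), value = TRUE)
  onset_u <- onset_timepoint(as.matrix(unadjusted_calls[, ucols, drop = FALSE]))
  onset_a <- onset_timepoint(as.matrix(adj[, acols, drop = FALSE]))
  onset <- ifelse(cls %in% c("composition", "mixed"), onset_u,
                  ifelse(cls == "regulation", onset_a, NA_character_))
  out <- data.frame(gene = unadjusted_calls$gene, class = cls, onset = onset,
                    stringsAsFactors = FALSE)
  un_flags <- unadjusted_calls[, ucols, drop = FALSE]
  colnames(un_flags) <- paste0("un_", ucols)
  adj_flags <- adj[, acols, drop = FALSE]
  colnames(adj_flags) <- paste0("adj_", acols)
  cbind(out, un_flags, adj_flags)
}

#' Onset Venn-style counts
#'
#' Tabulates, per combination of flagged timepoints, how many genes show
#' that pattern — the numeric content of an onset Venn diagram.
#'
#' @param calls a [call_pregnancy_associated()] result.
#' @return data.frame pattern (e.g. "T1+T2+T3"), n.
#' @export
onset_venn_counts <- function(calls) {
  fcols <- grep("^flag_", colnames(calls), value = TRUE)
  tp <- sub("^flag_", "", fcols)
  fl <- as.matrix(calls[, fcols, drop = FALSE])
  pat <- apply(fl, 1, function(f) paste(tp[f], collapse = "+"))
  pat <- pat[calls$flagged & pat != ""]
  if (length(pat) == 0)
    return(data.frame(pattern = character(0), n = integer(0)))
  tab <- table(pat)
  data.frame(pattern = names(tab), n = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Score mechanism classification against simulation truth
#'
#' Computes the truth-vs-predicted confusion matrix and a balanced accuracy
#' (mean per-class recall over the truth classes actually present). A truth
#' "regulation" gene counts as recovered when its screen label asserts
#' regulation involvement — "regulation" or "mixed" — because a gene with a
#' strong planted regulation effect remains significant in both the
#' adjusted and unadjusted screens and the paired-screen set algebra then
#' necessarily labels it "mixed"; the other classes are scored strictly.
#' `regulation_sensitivity` is the fraction of truth-regulation genes whose
#' label asserts regulation involvement (equivalently, that were called in
#' the adjusted screen).
#'
#' @param truth simulation truth data.frame (`gene`, `class`).
#' @param mechanism a [classify_mechanism()] result.
#' @return list `confusion` (table), `per_class_recall`,
#'   `balanced_accuracy`, `regulation_sensitivity`.
#' @export
mechanism_recovery <- function(truth, mechanism) {
  m <- mechanism[match(truth$gene, mechanism$gene), ]
  keep <- !is.na(m$class)
  tr <- truth$class[keep]; pr <- m$class[keep]
  confusion <- table(truth = tr, predicted = pr)
  recall_of <- function(cls) {
    in_cls <- tr == cls
    if (!any(in_cls)) return(NA_real_)
    ok <- switch(cls,
                 none = ,
                 null = pr[in_cls] == "none",
                 composition = pr[in_cls] == "composition",
                 mixed = pr[in_cls] == "mixed",
                 regulation = pr[in_cls] %in% c("regulation", "mixed"))
    mean(ok)
  }
  classes <- intersect(c("null", "composition", "mixed", "regulation"),
                       unique(tr))
  rec <- vapply(classes, recall_of, numeric(1))
  reg_sens <- if ("regulation" %in% classes) rec[["regulation"]] else NA_real_
  list(confusion = confusion,
       per_class_recall = rec,
       balanced_accuracy = mean(rec),
       regulation_sensitivity = reg_sens)
}

#' Postpartum reversion correlation
#'
#' Pearson correlation, over genes with a significant postpartum change,
#' between the within-pregnancy change (baseline to late pregnancy) and the
#' postpartum change (late pregnancy to postpartum). Values near -1 indicate
#' reversion to baseline after delivery.
#'
#' @param screen_t0_ref screen with T0 reference (supplies `log2FC_T3`).
#' @param screen_t3_ref screen releveled to T3 reference (supplies
#'   `log2FC_PP3` and the significance gate).
#' @param fdr,fc thresholds for the postpartum significance gate.
#' @return list `r` (Pearson correlation, NA if fewer than 3 genes qualify),
#'   `n` (genes used), `genes`.
#' @export
reversion_correlation <- function(screen_t0_ref, screen_t3_ref,
                                  fdr = 0.05, fc = 2) {
  calls_pp <- call_pregnancy_associated(screen_t3_ref, fdr = fdr, fc = fc,
                                        timepoints = "PP3")
  genes <- calls_pp$gene[calls_pp$flagged]
  if (length(genes) < 3) {
    warning("fewer than 3 genes significant for the postpartum contrast")
    return(list(r = NA_real_, n = length(genes), genes = genes))
  }
  x <- screen_t0_ref$log2FC_T3[match(genes, screen_t0_ref$gene)]
  y <- screen_t3_ref$log2FC_PP3[match(genes, screen_t3_ref$gene)]
  ok <- is.finite(x) & is.finite(y)
  list(r = stats::cor(x[ok], y[ok]), n = sum(ok), genes = genes[ok])
}
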