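#' Default pipeline configuration
#'
#' All tunables of the end-to-end synthetic-cohort analysis, with the
#' package's reference study design as defaults: 14 subjects at T0-T3 and
#' PP3, 2,000 genes, 8 cell types, a log-ratio composition shift of 1.0 on
#' the dominant (neutrophil-like) type during pregnancy, 10% of genes
#' regulated four-fold with postpartum reversion, FDR 0.05 and fold-change 2
#' calling thresholds, and the standard co-expression parameters (power 5,
#' merge cut 0.25, max outlier fraction 0.1).
#'
#' @param seed master integer seed; every stage derives its randomness from
#'   it.
#' @return nested named list understood by [run_pipeline()].
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(n_subjects = 14, n_genes = 2000, n_cell_types = 8,
                  timepoints = c("T0", "T1", "T2", "T3", "PP3"),
                  markers_per_type = 25, marker_fold = 50,
                  shift_size = 1.0, shift_type = 5L, frac_regulated = 0.10,
                  rho = log(4), tau = 0.3, phi_range = c(0.01, 0.5),
                  mixed_frac = 0),
    thresholds = list(fdr = 0.05, fc = 2, cpm_numerator = 10,
                      min_samples = 8, power = 5, merge_cut = 0.25,
                      max_p_outliers = 0.1, min_module_size = 30,
                      cut_height = 0.995, pc_fdr = 0.05,
                      pc_min_genes_fraction = 0.05),
    model = list(corstr = "independence", include_parity = FALSE),
    coexpr = list(run = TRUE, max_genes = 2000)
  )
}

#' Validate (and complete) a pipeline configuration
#'
#' Unknown keys at any level are rejected; missing keys are filled from
#' [default_config()]; basic sanity constraints (positive thresholds,
#' ordered timepoints starting at T0) are enforced.
#'
#' @param config nested list, e.g. parsed from YAML.
#' @return completed configuration list.
#' @export
validate_config <- function(config) {
  def <- default_config()
  check_keys <- function(x, ref, where) {
    unknown <- setdiff(names(x), names(ref))
    if (length(unknown))
      stop("unknown config key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
  }
  check_keys(config, def, "top level")
  for (sec in c("cohort", "thresholds", "model", "coexpr")) {
    if (!is.null(config[[sec]])) check_keys(config[[sec]], def[[sec]], sec)
    config[[sec]] <- utils::modifyList(def[[sec]], config[[sec]] %||% list())
  }
  config$seed <- as.integer(config$seed %||% def$seed)
  th <- config$thresholds
  if (any(unlist(th[c("fdr", "fc", "cpm_numerator", "min_samples", "power",
                      "merge_cut", "max_p_outliers")]) <= 0))
    stop("thresholds must be positive")
  tp <- config$cohort$timepoints
  if (tp[1] != "T0" || !all(tp %in% TIMEPOINT_LEVELS))
    stop("timepoints must start at T0 and use known labels")
  config
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return [validate_config()]-completed configuration.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full synthetic-cohort analysis
#'
#' simulate -> filter/normalize -> deconvolve + PC selection -> paired GEE
#' screens (unadjusted and PC-adjusted) -> fold-change calls, onset and
#' mechanism classification -> postpartum reversion -> co-expression modules
#' -> module and marker-set enrichment. All tables are written as TSV under
#' `outdir` together with a JSON run manifest; a rerun with the same config
#' reproduces every table bit-identically.
#'
#' @param config list from [default_config()] / [validate_config()].
#' @param outdir output directory (created if absent).
#' @param quiet suppress stage messages.
#' @return (invisibly) a list with all in-memory results.
#' @export
run_pipeline <- function(config = default_config(), outdir = "results",
                         quiet = FALSE) {
  config <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    say(sprintf("[%s] done in %.1fs", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  ch <- config$cohort; th <- config$thresholds

  sim <- stage("simulate", {
    s <- simulate_cohort(n_subjects = ch$n_subjects, n_genes = ch$n_genes,
                         n_cell_types = ch$n_cell_types,
                         timepoints = ch$timepoints,
                         markers_per_type = ch$markers_per_type,
                         marker_fold = ch$marker_fold,
                         shift_size = ch$shift_size,
                         shift_type = ch$shift_type,
                         frac_regulated = ch$frac_regulated, rho = ch$rho,
                         tau = ch$tau, phi_range = ch$phi_range,
                         mixed_frac = ch$mixed_frac, seed = config$seed)
    write_signature(s$signature, file.path(outdir, "signature.tsv"))
    write_counts(s$counts, file.path(outdir, "counts.tsv"))
    write_tsv(s$metadata, file.path(outdir, "metadata.tsv"))
    write_tsv(s$truth, file.path(outdir, "truth.tsv"))
    s
  })

  prep <- stage("preprocess", {
    counts <- filter_gene_types(sim$counts)
    counts <- filter_low_expression(counts, th$cpm_numerator, th$min_samples)
    factors <- tmm_factors(counts)
    write_tsv(data.frame(sample = names(factors$factors),
                         factor = unname(factors$factors),
                         lib_size = unname(factors$lib_sizes)),
              file.path(outdir, "norm_factors.tsv"))
    list(counts = counts, factors = factors,
         cpm = cpm_normalized(counts, factors),
         logcpm = cpm_normalized(counts, factors, log = TRUE))
  })

  deconv <- stage("deconvolve", {
    est <- estimate_proportions(prep$cpm, sim$signature)
    pcs <- proportion_pcs(est)
    sel <- select_pcs(pcs, prep$logcpm, fdr = th$pc_fdr,
                      min_genes_fraction = th$pc_min_genes_fraction)
    write_tsv(cbind(data.frame(sample = rownames(est$proportions)),
                    as.data.frame(est$proportions)),
              file.path(outdir, "proportions.tsv"))
    if (pcs$n_pcs > 0)
      write_tsv(cbind(data.frame(sample = rownames(pcs$scores)),
                      as.data.frame(pcs$scores)),
                file.path(outdir, "pc_scores.tsv"))
    say("  selected PCs: ", paste(sel, collapse = ", "))
    list(est = est, pcs = pcs, selected = sel)
  })

  screens <- stage("screen", {
    un <- run_screen(prep$counts, prep$factors, sim$metadata, pcs = NULL,
                     corstr = config$model$corstr,
                     include_parity = config$model$include_parity)
    sel_scores <- if (length(deconv$selected))
      deconv$pcs$scores[, deconv$selected, drop = FALSE] else NULL
    ad <- if (!is.null(sel_scores))
      run_screen(prep$counts, prep$factors, sim$metadata, pcs = sel_scores,
                 corstr = config$model$corstr,
                 include_parity = config$model$include_parity)
    else un  # no informative PCs: the adjusted model reduces to unadjusted
    write_tsv(un, file.path(outdir, "screen_unadjusted.tsv"))
    write_tsv(ad, file.path(outdir, "screen_adjusted.tsv"))
    list(unadjusted = un, adjusted = ad)
  })

  classify <- stage("classify", {
    calls_un <- call_pregnancy_associated(screens$unadjusted, th$fdr, th$fc)
    calls_ad <- call_pregnancy_associated(screens$adjusted, th$fdr, th$fc)
    mech <- classify_mechanism(calls_un, calls_ad)
    write_tsv(mech, file.path(outdir, "mechanism.tsv"))
    write_tsv(onset_venn_counts(calls_un),
              file.path(outdir, "venn_unadjusted.tsv"))
    write_tsv(onset_venn_counts(calls_ad),
              file.path(outdir, "venn_adjusted.tsv"))
    list(calls_un = calls_un, calls_ad = calls_ad, mechanism = mech)
  })

  reversion <- if ("PP3" %in% ch$timepoints) stage("reversion", {
    sc_t3 <- run_screen(prep$counts, prep$factors, sim$metadata, pcs = NULL,
                        corstr = config$model$corstr,
                        include_parity = config$model$include_parity,
                        ref = "T3")
    rev <- reversion_correlation(screens$unadjusted, sc_t3,
                                 fdr = th$fdr, fc = th$fc)
    write_tsv(data.frame(r = rev$r, n = rev$n),
              file.path(outdir, "reversion.tsv"))
    rev
  }) else NULL

  modules <- if (isTRUE(config$coexpr$run)) stage("coexpress", {
    expr <- prep$logcpm
    if (nrow(expr) > config$coexpr$max_genes) {
      keep <- order(-apply(expr, 1, stats::var))[seq_len(config$coexpr$max_genes)]
      expr <- expr[sort(keep), , drop = FALSE]
    }
    ma <- coexpression_modules(expr, beta = th$power,
                               max_p_outliers = th$max_p_outliers,
                               min_module_size = th$min_module_size,
                               cut_height = th$cut_height,
                               merge_cut = th$merge_cut)
    write_tsv(data.frame(gene = names(ma$labels), module = unname(ma$labels)),
              file.path(outdir, "modules.tsv"))
    ma
  }) else NULL

  enrich <- stage("enrich", {
    stage_lists <- list()
    on_un <- onset_timepoint(as.matrix(
      classify$calls_un[, grep("^flag_", colnames(classify$calls_un))]))
    for (tpn in c("T1", "T2", "T3"))
      stage_lists[[tpn]] <- classify$calls_un$gene[!is.na(on_un) & on_un == tpn]
    mod_tab <- if (!is.null(modules))
      module_set_enrichment(modules, stage_lists) else NULL
    if (!is.null(mod_tab))
      write_tsv(mod_tab, file.path(outdir, "module_enrichment.tsv"))
    ## marker gene sets from the signature, as a built-in GMT round trip
    mt <- marker_types(sim$signature)
    marker_sets <- split(names(mt)[!is.na(mt)], mt[!is.na(mt)])
    gmt_path <- file.path(outdir, "marker_sets.gmt")
    write_gmt(marker_sets, gmt_path)
    collection <- list(sets = read_gmt(gmt_path),
                       universe = rownames(prep$counts))
    flagged <- classify$calls_un$gene[classify$calls_un$flagged]
    marker_tab <- enrich_collection(flagged, collection)
    write_tsv(marker_tab, file.path(outdir, "marker_enrichment.tsv"))
    list(modules = mod_tab, markers = marker_tab)
  })

  manifest <- list(package_version = as.character(utils::packageVersion("longidecomp")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config = config,
                   n_genes_filtered = nrow(prep$counts),
                   n_flagged_unadjusted = sum(classify$calls_un$flagged),
                   n_flagged_adjusted = sum(classify$calls_ad$flagged),
                   mechanism_counts = as.list(table(classify$mechanism$class)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(sim = sim, prep = prep, deconv = deconv, screens = screens,
                 classify = classify, reversion = reversion,
                 modules = modules, enrich = enrich, manifest = manifest))
}
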