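#' Ordered longitudinal timepoint labels
#'
#' Pre-baseline (T0), the three trimesters (T1-T3) and the postpartum visits
#' at 3, 6 and 9 months (PP3, PP6, PP9). All timepoint arguments in the
#' package must be drawn from this set, with T0 first.
#'
#' @export
TIMEPOINT_LEVELS <- c("T0", "T1", "T2", "T3", "PP3", "PP6", "PP9")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic cell-type signature matrix
#'
#' Builds a genes x cell-types matrix of linear-scale reference expression in
#' which each cell type has `markers_per_type` designated marker genes whose
#' expression in that type is at least `marker_fold` times its expression in
#' every other type. Non-marker genes get correlated lognormal expression
#' across types. The matrix plays the role a published immune signature
#' (e.g. LM22) plays in deconvolution of real blood data.
#'
#' @param n_genes number of genes (rows); must be at least
#'   `n_cell_types * markers_per_type`.
#' @param n_cell_types number of cell types (columns).
#' @param markers_per_type designated marker genes per type.
#' @param marker_fold minimum fold separating a marker's own-type expression
#'   from all other types; must be >= 1 (>= 5 to satisfy the marker
#'   invariant this package assumes downstream).
#' @param seed integer RNG seed; identical seeds give identical matrices.
#' @return numeric matrix with gene rownames and cell-type colnames, plus a
#'   `marker_type` attribute: a character vector (NA for non-markers) naming
#'   the type each marker gene tags.
#' @export
generate_signature <- function(n_genes, n_cell_types, markers_per_type = 10,
                               marker_fold = 10, seed = 1L) {
  if (n_genes <= 0 || n_cell_types <= 0 || markers_per_type <= 0)
    stop("dimensions must be positive")
  if (marker_fold < 1) stop("marker_fold must be >= 1")
  if (n_genes < n_cell_types * markers_per_type)
    stop("n_genes must be >= n_cell_types * markers_per_type")
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  types <- sprintf("celltype%02d", seq_len(n_cell_types))
  ## base abundance per gene, mild type-to-type variation
  base <- exp(stats::rnorm(n_genes, mean = log(30), sd = 1))
  S <- base * matrix(exp(stats::rnorm(n_genes * n_cell_types, 0, 0.3)),
                     n_genes, n_cell_types)
  marker_type <- rep(NA_character_, n_genes)
  idx <- 0L
  for (c in seq_len(n_cell_types)) {
    rows <- idx + seq_len(markers_per_type)
    idx <- idx + markers_per_type
    ## force own-type expression to marker_fold x the max over other types
    other_max <- apply(S[rows, -c, drop = FALSE], 1, max)
    S[rows, c] <- marker_fold * other_max
    marker_type[rows] <- types[c]
  }
  dimnames(S) <- list(genes, types)
  stopifnot(all(S > 0))
  attr(S, "marker_type") <- stats::setNames(marker_type, genes)
  S
}

#' Marker-type annotation of a signature matrix
#'
#' @param signature matrix from [generate_signature()] (or any matrix with a
#'   `marker_type` attribute).
#' @return named character vector, NA for non-marker genes.
#' @export
marker_types <- function(signature) {
  mt <- attr(signature, "marker_type")
  if (is.null(mt)) stop("signature has no marker_type annotation")
  mt
}

#' Generate per-subject cell-type composition trajectories
#'
#' Each subject receives a Dirichlet baseline composition; at every timepoint
#' the baseline is perturbed on the additive log-ratio scale by
#' `logit_shifts` and renormalized to the simplex, so subjects keep their
#' rank ordering while rows always sum to one. A positive shift on one type
#' (e.g. a neutrophil-like population rising during pregnancy) dilutes the
#' remaining types proportionally.
#'
#' @param n_subjects number of subjects.
#' @param timepoints character vector, subset of [TIMEPOINT_LEVELS] with
#'   "T0" first.
#' @param baseline_alpha positive Dirichlet concentration vector, one entry
#'   per cell type (names become the cell-type labels).
#' @param logit_shifts numeric matrix timepoints x cell types of log-ratio
#'   shifts (0 = no change); NULL means all zero. Rows for timepoints not in
#'   `timepoints` are ignored.
#' @param seed integer RNG seed.
#' @return 3-d array subjects x timepoints x cell types with dimnames; rows
#'   (fixed subject and timepoint) sum to 1. Attribute `shifted_types` names
#'   the cell types given any nonzero planted shift.
#' @export
generate_compositions <- function(n_subjects, timepoints, baseline_alpha,
                                  logit_shifts = NULL, seed = 1L) {
  if (any(baseline_alpha <= 0)) stop("baseline_alpha entries must be > 0")
  if (!all(timepoints %in% TIMEPOINT_LEVELS))
    stop("unknown timepoint labels: ",
         paste(setdiff(timepoints, TIMEPOINT_LEVELS), collapse = ", "))
  if (timepoints[1] != "T0") stop("timepoints must start at T0")
  n_types <- length(baseline_alpha)
  types <- names(baseline_alpha) %||% sprintf("celltype%02d", seq_len(n_types))
  shifts <- matrix(0, length(timepoints), n_types,
                   dimnames = list(timepoints, types))
  if (!is.null(logit_shifts)) {
    common_t <- intersect(rownames(logit_shifts), timepoints)
    common_c <- intersect(colnames(logit_shifts), types)
    if (is.null(rownames(logit_shifts)) || is.null(colnames(logit_shifts)))
      stop("logit_shifts must have timepoint rownames and cell-type colnames")
    shifts[common_t, common_c] <- logit_shifts[common_t, common_c]
  }
  set.seed(seed)
  subjects <- sprintf("subj%02d", seq_len(n_subjects))
  out <- array(NA_real_, dim = c(n_subjects, length(timepoints), n_types),
               dimnames = list(subjects, timepoints, types))
  for (i in seq_len(n_subjects)) {
    g <- stats::rgamma(n_types, shape = baseline_alpha, rate = 1)
    p0 <- g / sum(g)
    for (t in seq_along(timepoints)) {
      p <- p0 * exp(shifts[t, ])
      out[i, t, ] <- p / sum(p)
    }
  }
  attr(out, "shifted_types") <- types[colSums(abs(shifts)) > 0]
  out
}

#' Construct a regulation plan for the count generator
#'
#' Chooses a set of regulated genes (disjoint from the marker genes of
#' composition-shifted types unless `allow_markers`) and assigns each a
#' multiplicative regulation trajectory on the natural-log scale: zero at
#' baseline, +/- `rho` from a randomly drawn onset trimester through T3, and
#' (by default) back to zero at the postpartum timepoints, so planted effects
#' revert after delivery.
#'
#' @param signature signature matrix (defines the gene universe).
#' @param timepoints timepoints the cohort will be sampled at.
#' @param frac_regulated fraction of genes receiving a regulation effect.
#' @param rho effect magnitude on the natural-log scale (default `log(4)`).
#' @param tau SD of the gene-by-subject lognormal random effect.
#' @param phi_range per-gene NB dispersions are drawn log-uniformly from this
#'   interval; variance model is `mu + phi * mu^2`.
#' @param lib_size_meanlog,lib_size_sdlog lognormal library-size parameters.
#' @param onsets trimesters at which regulation may switch on.
#' @param revert_pp if TRUE planted effects vanish at PP3/PP6/PP9.
#' @param mixed_frac fraction of *marker genes of shifted types* additionally
#'   given a regulation effect (truth class "mixed"); requires the shifted
#'   types to be known when counts are generated.
#' @param seed integer RNG seed.
#' @return list with elements `rho` (genes x timepoints matrix, natural log),
#'   `tau`, `phi` (per-gene), `lib_size_meanlog`, `lib_size_sdlog`,
#'   `mixed_frac`, `seed`.
#' @export
default_regulation_plan <- function(signature,
                                    timepoints = c("T0", "T1", "T2", "T3", "PP3"),
                                    frac_regulated = 0.10,
                                    rho = log(4),
                                    tau = 0.3,
                                    phi_range = c(0.01, 0.5),
                                    lib_size_meanlog = log(3e6),
                                    lib_size_sdlog = 0.2,
                                    onsets = c("T1", "T2", "T3"),
                                    revert_pp = TRUE,
                                    mixed_frac = 0,
                                    seed = 1L) {
  genes <- rownames(signature)
  set.seed(seed)
  rho_mat <- matrix(0, length(genes), length(timepoints),
                    dimnames = list(genes, timepoints))
  mt <- attr(signature, "marker_type")
  eligible <- if (is.null(mt)) genes else genes[is.na(mt)]
  n_reg <- round(frac_regulated * length(genes))
  n_reg <- min(n_reg, length(eligible))
  reg_genes <- sort(sample(eligible, n_reg))
  onsets <- intersect(onsets, timepoints)
  trimesters <- intersect(c("T1", "T2", "T3"), timepoints)
  pp <- intersect(c("PP3", "PP6", "PP9"), timepoints)
  for (g in reg_genes) {
    onset <- sample(onsets, 1)
    sgn <- sample(c(-1, 1), 1)
    active <- trimesters[match(trimesters, TIMEPOINT_LEVELS) >=
                           match(onset, TIMEPOINT_LEVELS)]
    rho_mat[g, active] <- sgn * rho
    if (!revert_pp && length(pp)) rho_mat[g, pp] <- sgn * rho
  }
  phi <- exp(stats::runif(length(genes), log(phi_range[1]), log(phi_range[2])))
  names(phi) <- genes
  list(rho = rho_mat, tau = tau, phi = phi,
       lib_size_meanlog = lib_size_meanlog, lib_size_sdlog = lib_size_sdlog,
       mixed_frac = mixed_frac, seed = seed)
}

## Truth classes are a pure function of signature markers, planted
## composition shifts and the regulation plan, so they can be recomputed and
## checked against the stored ledger.
recompute_truth_classes <- function(signature, compositions, plan) {
  mt <- attr(signature, "marker_type")
  shifted <- attr(compositions, "shifted_types") %||% character(0)
  genes <- rownames(signature)
  is_marker_shift <- !is.na(mt) & mt %in% shifted
  is_reg <- rowSums(abs(plan$rho)) > 0
  cls <- rep("null", length(genes))
  cls[is_marker_shift & !is_reg] <- "composition"
  cls[!is_marker_shift & is_reg] <- "regulation"
  cls[is_marker_shift & is_reg] <- "mixed"
  stats::setNames(cls, genes)
}

#' Generate a longitudinal bulk RNA-seq count matrix with known truth
#'
#' Samples counts from the generative model
#' \deqn{\mu_{git} = N_{it}\, e^{b_{gi}}\, e^{\rho_{gt}}
#'   \frac{\sum_c p_{cit} S_{gc}}{\sum_{g'}\sum_c p_{cit} S_{g'c}},}
#' where \eqn{N_{it}} is the library size, \eqn{b_{gi} \sim N(0,\tau^2)} a
#' gene-by-subject random effect inducing within-subject correlation,
#' \eqn{\rho_{gt}} the planted regulation effect (zero at T0), \eqn{p} the
#' composition trajectories and \eqn{S} the signature. Counts are negative
#' binomial with variance \eqn{\mu + \phi_g \mu^2}.
#'
#' @param signature matrix from [generate_signature()].
#' @param compositions array from [generate_compositions()].
#' @param plan list from [default_regulation_plan()] (or same shape).
#' @param age_params list with `mean` and `sd` of subject age at conception
#'   (years), truncated above 18. Default mean 28.9, sd 1.0.
#' @param parity_probs sampling probabilities for parity 0/1/2.
#' @param seed integer RNG seed.
#' @return list with `counts` (integer matrix genes x samples, with a
#'   `gene_type` attribute, all "protein_coding" unless the caller edits it),
#'   `metadata` (data.frame sample_id, subject_id, timepoint, age, parity),
#'   and `truth` (data.frame gene, class, marker_type, regulated; with the
#'   composition array, rho matrix and seed as attributes).
#' @export
generate_counts <- function(signature, compositions, plan,
                            age_params = list(mean = 28.9, sd = 1.0),
                            parity_probs = c(7, 6, 1) / 14,
                            seed = 1L) {
  genes <- rownames(signature)
  if (!identical(genes, rownames(plan$rho)))
    stop("gene sets of signature and plan differ")
  if (any(plan$phi <= 0)) stop("phi must be > 0")
  subjects <- dimnames(compositions)[[1]]
  timepoints <- dimnames(compositions)[[2]]
  types <- dimnames(compositions)[[3]]
  if (!identical(colnames(signature), types))
    stop("cell types of signature and compositions differ")
  if (!all(timepoints %in% colnames(plan$rho)))
    stop("plan$rho lacks columns for some timepoints")
  if (any(abs(plan$rho[, "T0"]) > 0)) stop("rho must be 0 at T0")

  set.seed(seed)
  ## optionally promote some shifted-type markers to "mixed" (rho on top)
  shifted <- attr(compositions, "shifted_types") %||% character(0)
  mt <- attr(signature, "marker_type")
  if ((plan$mixed_frac %||% 0) > 0 && length(shifted) && !is.null(mt)) {
    cand <- genes[!is.na(mt) & mt %in% shifted]
    n_mix <- round(plan$mixed_frac * length(cand))
    if (n_mix > 0) {
      mix_genes <- sort(sample(cand, n_mix))
      tr <- intersect(c("T1", "T2", "T3"), timepoints)
      for (g in mix_genes)
        plan$rho[g, tr] <- sample(c(-1, 1), 1) * max(abs(plan$rho))
    }
  }

  n_g <- length(genes)
  b <- matrix(stats::rnorm(n_g * length(subjects), 0, plan$tau),
              n_g, length(subjects), dimnames = list(genes, subjects))
  lib <- matrix(exp(stats::rnorm(length(subjects) * length(timepoints),
                                 plan$lib_size_meanlog, plan$lib_size_sdlog)),
                length(subjects), length(timepoints),
                dimnames = list(subjects, timepoints))
  sample_ids <- as.vector(outer(subjects, timepoints,
                                function(s, t) paste(s, t, sep = "_")))
  counts <- matrix(0L, n_g, length(sample_ids),
                   dimnames = list(genes, sample_ids))
  meta <- data.frame(sample_id = sample_ids,
                     subject_id = rep(subjects, times = length(timepoints)),
                     timepoint = rep(timepoints, each = length(subjects)),
                     stringsAsFactors = FALSE)
  ## ages/parity per subject
  age <- stats::rnorm(length(subjects), age_params$mean, age_params$sd)
  while (any(age <= 18))
    age[age <= 18] <- stats::rnorm(sum(age <= 18), age_params$mean, age_params$sd)
  names(age) <- subjects
  parity <- stats::setNames(
    sample(0:2, length(subjects), replace = TRUE, prob = parity_probs),
    subjects)
  meta$age <- age[meta$subject_id]
  meta$parity <- parity[meta$subject_id]

  for (t in seq_along(timepoints)) {
    for (i in seq_along(subjects)) {
      p <- compositions[i, t, ]
      mix <- as.vector(signature %*% p)
      mu <- lib[i, t] * exp(b[, i]) * exp(plan$rho[genes, timepoints[t]]) *
        mix / sum(mix)
      y <- stats::rnbinom(n_g, mu = mu, size = 1 / plan$phi)
      counts[, paste(subjects[i], timepoints[t], sep = "_")] <- y
    }
  }
  storage.mode(counts) <- "integer"
  attr(counts, "gene_type") <- stats::setNames(
    rep("protein_coding", n_g), genes)

  cls <- recompute_truth_classes(signature, compositions, plan)
  truth <- data.frame(gene = genes,
                      class = unname(cls),
                      marker_type = unname(if (is.null(mt))
                        rep(NA_character_, n_g) else mt),
                      regulated = unname(rowSums(abs(plan$rho)) > 0),
                      stringsAsFactors = FALSE)
  attr(truth, "compositions") <- compositions
  attr(truth, "rho") <- plan$rho
  attr(truth, "seed") <- seed
  list(counts = counts, metadata = meta, truth = truth)
}

#' Simulate a complete default cohort
#'
#' Convenience wrapper reproducing the package's reference study design: 14
#' subjects sampled at T0-T3 and PP3, 2,000 genes, 8 cell types of graded
#' abundance (the first, most abundant, playing the neutrophil-like
#' background role), with one modest-abundance cell type whose proportion
#' rises during pregnancy (log-odds shift `shift_size` at T1-T3, reverting
#' at PP3) so its marker genes show a bulk fold change straddling the
#' two-fold calling threshold, and 10% of non-marker genes regulated at
#' +/- `rho` with varying onset, reverting postpartum.
#'
#' @param n_subjects,n_genes,n_cell_types cohort dimensions.
#' @param timepoints sampling timepoints.
#' @param markers_per_type,marker_fold signature parameters; the default
#'   fold of 50 gives markers the strong type specificity of, e.g.,
#'   granulocyte defensins, so composition shifts are visible in bulk.
#' @param shift_size log-ratio shift on the shifted cell type at T1-T3.
#' @param shift_type index of the shifted cell type (default 5, baseline
#'   share about 8%).
#' @param frac_regulated,rho,tau,phi_range regulation-plan parameters.
#' @param mixed_frac fraction of shifted-type markers also regulated.
#' @param seed integer RNG seed; sub-stages derive small offsets from it.
#' @return list with `signature`, `compositions`, `plan`, `counts`,
#'   `metadata`, `truth`.
#' @export
simulate_cohort <- function(n_subjects = 14, n_genes = 2000, n_cell_types = 8,
                            timepoints = c("T0", "T1", "T2", "T3", "PP3"),
                            markers_per_type = 25, marker_fold = 50,
                            shift_size = 1.0, shift_type = 5L,
                            frac_regulated = 0.10, rho = log(4), tau = 0.3,
                            phi_range = c(0.01, 0.5), mixed_frac = 0,
                            seed = 1L) {
  seed <- as.integer(seed)
  sig <- generate_signature(n_genes, n_cell_types, markers_per_type,
                            marker_fold, seed = seed)
  types <- colnames(sig)
  alpha <- stats::setNames(
    c(30, 15, 10, 8, 6, 4, 3, 2, rep(2, max(0, n_cell_types - 8)))[
      seq_len(n_cell_types)], types)
  shifts <- matrix(0, length(timepoints), n_cell_types,
                   dimnames = list(timepoints, types))
  tr <- intersect(c("T1", "T2", "T3"), timepoints)
  shift_type <- min(as.integer(shift_type), n_cell_types)
  shifts[tr, types[shift_type]] <- shift_size
  comps <- generate_compositions(n_subjects, timepoints, alpha,
                                 logit_shifts = shifts, seed = seed + 1L)
  plan <- default_regulation_plan(sig, timepoints,
                                  frac_regulated = frac_regulated, rho = rho,
                                  tau = tau, phi_range = phi_range,
                                  mixed_frac = mixed_frac, seed = seed + 2L)
  sim <- generate_counts(sig, comps, plan, seed = seed + 3L)
  c(list(signature = sig, compositions = comps, plan = plan), sim)
}
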