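# longidecomp

Longitudinal whole-blood RNA-seq mixes two signals: when the same subjects
are sampled repeatedly — e.g. before pregnancy (T0), each trimester
(T1–T3) and postpartum (PP3) — a gene's expression change can reflect a
shift in circulating cell-type proportions, transcriptional regulation
within cells, or both. `longidecomp` is an R package for separating the
two, aimed at analysts of repeated-measures bulk transcriptomics who need
the whole chain in one tested place: normalization, deconvolution,
composition-adjusted longitudinal screens, mechanism classification,
co-expression modules and set enrichment — plus a synthetic-cohort
generator with a ground-truth ledger, so every stage is validated by
recovery of planted effects.

## The model

Counts are generated (and modeled) as library-scaled signature mixtures
with multiplicative regulation:

$$\mu_{git} = N_{it}\, e^{b_{gi}}\, e^{\rho_{gt}}\,
\frac{\sum_c p_{cit} S_{gc}}{\sum_{g'}\sum_c p_{cit} S_{g'c}},
\qquad \mathrm{Var}(y) = \mu + \phi_g\mu^2,$$

with signature $S$, per-sample composition $p$ on the simplex, regulation
effects $\rho$ (zero at baseline), subject random effects
$b_{gi}\sim N(0,\tau^2)$ and per-gene NB dispersion $\phi_g$.

Inference per gene is a log-link GEE with NB variance, timepoint factor
plus covariates, offset $\log(N_k f_k)$ (TMM-scaled library size), robust
sandwich covariance $B^{-1}MB^{-1}$ clustered by subject, and a joint Wald
test of the timepoint profile with BH FDR across genes. The screen is run
twice — with and without principal components of the deconvolved cell-type
proportions as covariates — and each gene significant at FDR < 0.05 with
fold change ≥ 2 is classified by set algebra: significant only unadjusted →
**composition**; only adjusted → **regulation**; both → **mixed**.

## Worked example

The numbered scripts under `analysis/` run the full study on the default
synthetic cohort (14 subjects × 5 timepoints × 2,000 genes × 8 cell
types). `Rscript analysis/01_simulate.R` through `07_enrich.R` print, in
order:

```
cohort: 2000 genes x 70 samples (14 subjects)
truth classes: composition 25, null 1775, regulation 200
genes: 2000 -> 2000 after biotype + expression filters
TMM reference sample: subj01_PP3; factor range 0.928 - 1.086
cell types with significant proportion changes vs T0: celltype01, ..., celltype06
proportion PCs: 7; selected as covariates: 1, 2, 3, 4, 5, 6
genes with q < 0.05 (any fold change): unadjusted 650, adjusted 637
pregnancy-associated (FDR<0.05, FC>=2): unadjusted 229, adjusted 239
mechanism classes: composition 23, mixed 206, none 1738, regulation 33
truth recovery: balanced accuracy 0.953, regulation sensitivity 1
postpartum reversion: r = -0.995 over 218 genes significant for the PP3-vs-T3 contrast
6 modules (1509 genes unassigned): turquoise 135, blue 99, ...
module-stage enrichments at FDR < 0.05: T1 turquoise 7.3e-36; ...
top marker-set enrichment: celltype05 (fold 7, q = 3.9e-18)
```

Reading: the generator planted a composition shift on `celltype05` and
four-fold regulation on 200 genes. The paired screens recover the planted
mechanisms with balanced accuracy 0.95 — the 23 genes called
`composition` are markers of the shifted type, the flagged genes are
enriched 7-fold in that type's marker set, and because all planted effects
revert after delivery, the T0→T3 and T3→PP3 fold changes correlate at
−0.995. The same machinery is available programmatically:

```r
library(longidecomp)
res <- run_pipeline(default_config(seed = 1), outdir = "results/run")
table(res$classify$mechanism$class)
```

Tables land in the output directory as TSV together with a JSON manifest
recording seeds, thresholds and versions; identical configs reproduce
every table bit-identically.

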