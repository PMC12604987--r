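# ctgsurv

Cell-type-aware graph transformer survival modelling on clinical
patient-similarity networks, with gene-level hazard attribution and the
rule-based companion statistics of an integrative tumour-transcriptomics
workflow.

## What problem this solves

Bulk tumour cohorts (e.g. glioblastoma) come with censored survival
outcomes, mixed-type clinical covariates, and expression profiles that are
mixtures of malignant cell states. `ctgsurv` is for analysts who want a
survival model that (i) uses clinical similarity between patients as an
explicit graph, (ii) encodes expression through cell-state signatures so the
model's first layer is biologically legible, and (iii) explains its risk
scores gene by gene instead of being a black box.

The core model: patients are nodes of a graph built from clinical
covariates (Gower distance → self-tuning local-scaling kernel
S<sub>ij</sub> = exp(−d<sub>ij</sub>²/σ<sub>i</sub>σ<sub>j</sub>) →
mutual 5-NN filtering → minimum-spanning-tree backbone guaranteeing
connectivity). Standardized expression x is projected onto signature units
z<sub>s</sub> = Σ<sub>g</sub> M<sub>gs</sub> W<sub>gs</sub> x<sub>g</sub> + b<sub>s</sub>
through a binary mask M (genes influence only their own signatures —
exactly), lifted to an embedding with a dense residual bypass, refined by
transformer layers whose multi-head attention is restricted to each
patient's graph neighbourhood, and read out by a Cox proportional-hazards
head trained with the negative log partial likelihood
−Σ<sub>i:event</sub> [η<sub>i</sub> − log Σ<sub>j: t<sub>j</sub>≥t<sub>i</sub></sub> e<sup>η<sub>j</sub></sup>]
under Adam with dropout and early stopping on validation concordance.

Risk is attributed to genes by "hazard contours": the model's predicted
hazard over a grid of (own expression, graph-neighbourhood expression) for
each gene, summarized by the slope along the diagonal and classified as
risk-enhancing (RMHZ, high expression → high hazard) or risk-mitigating
(MHZ, low expression → high hazard).

Also included, because the surrounding workflow needs them: Wilcoxon
rank-sum marker selection (log2FC > 1, BH-adjusted P < 0.05), CNV-score
tumour calling (reference mean + 1.5 or 2 s.d.), relative-expression-
ordering (REO) reversal tests with Fisher's exact test, dual-corroborated
DEG filtering, multi-evidence gene convergence, IHC composite scoring
(intensity × proportion, 0–12), and a synthetic-cohort generator with known
Weibull proportional-hazards ground truth.

## Worked example

```r
library(ctgsurv)

## a TCGA-like synthetic cohort: 240 patients, 300 genes, six cell states,
## survival driven by the MES2-like fraction, 30% censoring
cohort <- simulate_cohort(cohort_config(seed = 1))
graph  <- build_patient_graph(cohort$clinical)          # clinical 5-NN + MST
mask   <- signature_mask(cohort$signatures, rownames(cohort$expression))

fit  <- train_survival_gnn(cohort$expression, cohort$clinical, graph, mask,
                           model_config(seed = 2))
fit
#> ctg_model: 300 genes, 6 signatures, 2 layers x 4 heads (d=64)
#>   selected epoch 0 of 21; validation concordance 0.684

risk <- predict_risk(fit, cohort$expression, graph)
test <- fit$split$test
cl   <- cohort$clinical[match(test, cohort$clinical$patient_id), ]
concordance_index(risk[test], cl$time, cl$event)
#> [1] 0.7296137
median_split_logrank(risk[test], cl$time, cl$event)$p_value
#> [1] 0.0006734657

## which genes drive risk, and in which direction?
rk <- rank_genes(fit, cohort$expression, graph,
                 genes = cohort$signatures[["MES2-like"]][1:5],
                 grid = seq(-2, 2, length.out = 9), neutral_band = 0.005)
rk$table
#>        gene      slope  magnitude class
#> 1 gene_0001 0.01449869 0.01449869  RMHZ
#> 2 gene_0003 0.01297014 0.01297014  RMHZ
#> 3 gene_0002 0.01164193 0.01164193  RMHZ
#> 4 gene_0004 0.01063869 0.01063869  RMHZ
#> 5 gene_0005 0.01006270 0.01006270  RMHZ
```

Held-out concordance of 0.73, near the true linear predictor's (~0.70
population value under these conditions), means the network recovered the
planted fraction-mediated signal; "selected epoch 0" says early stopping
kept the warm-started ridge readout because no fine-tuning epoch beat it on
validation concordance. The log-rank p-value tests the median-risk split on
the 48 test patients. `RMHZ` on MES2-like genes reproduces the planted
positive log-hazard loading; the slope scale (~0.01) is the per-gene share
of a 40-gene signature's effect, hence the tight neutral band (see the
methods vignette).

The rule-based statistics are one-liners:

```r
ihc_score(3, 4)                                   # 12, the scheme's maximum
cnv_call(scores, reference_ids, k_sd = 1.5)       # tumour/normal calls
reo_reversal_test(case_mat, reo_stable_pairs(ref_mat))
```

## Scope

The package does not infer CNV profiles from expression, fit deconvolution
or co-expression-module models, render figures beyond CSV exports, or
require a GPU; cohorts are expected to be hundreds, not tens of thousands,
of patients. See the methods vignette (`vignettes/ctgsurv-methods.Rmd`) for
the model's assumptions, parameter meanings, and known limitations.
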