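# amniotime

Analysis of the amniotic fluid cell-free transcriptome in spontaneous
preterm labor, and prediction of the time from amniocentesis to delivery.

Women sampled after an episode of preterm labor split into those who deliver
within 24 h of the amniocentesis and those who deliver later, and
intra-amniotic inflammation leaves a strong signature in the cell-free RNA
of the fluid. `amniotime` implements the full analysis chain for such a
cohort, for transcriptomics analysts working with gene-level log2 expression
matrices:

* **Preprocessing** — additive batch-effect removal by gene-wise linear
  models with sum-to-zero batch coding (protected biological covariates are
  preserved), and PCA of the gene-centred matrix.
* **Differential expression** — gene-wise OLS with empirical-Bayes variance
  moderation: a scaled inverse-chi-square prior `(d0, s0²)` on the gene
  variances, estimated by moment matching on `log s²` via trigamma
  inversion; posterior variances `(d0·s0² + d·s²)/(d0 + d)`; moderated t
  with `d0 + d` df; calls at fold change > 1.25 and BH q < 0.1.
* **Signatures** — tissue/cell-type specific gene sets from a reference
  atlas (median ≥ 30× all other tissues), per-sample Z-scores standardised
  against the term-delivery reference group and averaged over the top 20
  signature genes, compared between groups at q < 0.05.
* **Enrichment** — upper-tail hypergeometric tests of DE lists against GMT
  gene-set collections, BH-corrected.
* **Prediction** — sparse HSIC (HSIC-lasso) feature selection
  `min_{a≥0} ½‖L̄ − Σ_g a_g K̄_g‖²_F + λ‖a‖₁` over per-gene Gaussian grams,
  followed by a 1000-tree random forest, both re-run inside every
  leave-one-out fold; Spearman ρ, RMSE (weeks) and AUROC at the 24 h /
  1 week / 2 week horizons; selection stability (Jaccard, Cohen's kappa)
  and a binomial-test consensus gene list.
* **Clinical table** — Welch's t and two-sided Fisher's exact tests with
  median (IQR) and n (%) summaries.
* **Synthetic cohorts** — a generator that plants a latent inflammation
  axis driving both a response-gene block and shorter time-to-delivery,
  with batch structure, a tissue atlas and annotated gene sets, so every
  stage is testable without external data.

## Worked example

```r
library(amniotime)

co <- generate_cohort(sim_config(seed = 1))
co
#> Synthetic amniotic fluid cohort
#>   2000 genes x 38 samples (10 imminent <=24h, 28 later)
#>   200 response genes coupled to the inflammation axis; 2 batches

expr <- remove_batch_effects(co$expression, co$samples$batch,
                             protect = de_design(co$samples$group)[, 2, drop = FALSE])
de <- differential_expression(expr, co$samples$group)
de
#> Differential expression: 2000 genes tested, 207 called (124 up, 83 down)
#>   thresholds: fold change > 1.25, q < 0.1; prior df 3.77, prior var 0.0508

cv <- loocv_ttd(expr, co$samples$time_to_delivery, target_size = 50,
                n_trees = 1000, seed = 1)
evaluate_predictions(cv)
#> Spearman rho = 0.82 (p = 3.61e-10), RMSE = 1.52 weeks
#>   AUROC: 0.142857wk 0.99, 1wk 0.96, 2wk 0.86

selection_stability(cv$fold_sets, rownames(expr))
#> Selection stability over 38 folds: mean Jaccard 0.66, mean kappa 0.78

fisher_exact_2x2(matrix(c(8, 2, 8, 20), 2, byrow = TRUE))
#> [1] 0.008206107
```

Reading the output: 207 of 2000 genes are called differentially expressed
between the imminent- and later-delivery groups (the cohort plants 200 true
response genes at a two-fold change, so sensitivity is high and the false
discovery proportion small); the estimated variance-prior hyperparameters
(3.77, 0.0508) recover the generator's (4, 0.05). The leave-one-out CV —
feature selection repeated inside every fold — predicts time-to-delivery
with ρ = 0.82 and a 1.5-week RMSE, and ranks imminent (≤ 24 h) deliveries
at AUROC 0.99. The per-fold selected gene sets overlap strongly
(Jaccard 0.66, kappa 0.78). The last line reproduces the 0.008 p-value of
the 8/10-vs-8/28 amniotic-fluid IL-6 contingency table.

## Scope

The pipeline starts at a gene-level log2 expression matrix; probe-level
summarisation/normalisation, live gene-ontology lookups and
protein-interaction networks are out of scope. See the methods vignette
(`vignettes/amniotime-methods.Rmd`) for the models, assumptions, parameter
defaults and design decisions.
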