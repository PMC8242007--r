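---
title: "Methods: amniotic fluid cell-free transcriptome analysis and time-to-delivery prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amniotic fluid cell-free transcriptome analysis and time-to-delivery prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Women who present with an episode of spontaneous preterm labor differ widely
in how soon they deliver: some within a day of the diagnostic amniocentesis,
others weeks later. Amniotic fluid cell-free RNA samples the transcriptional
state of the fetus and gestational tissues, and intra-amniotic inflammation —
the biological driver of imminent delivery in a large fraction of cases —
leaves a strong imprint on it. `amniotime` implements the complete analysis
chain for such a cohort: preprocessing, differential expression between women
delivering within 24 h of amniocentesis and those delivering later, tissue
and placental cell-type signature scoring, gene-set enrichment, and
cross-validated prediction of the time from amniocentesis to delivery, plus
the clinical characteristics table. Because raw cohorts of this kind are not
generally available, the package ships a synthetic cohort generator that
reproduces the statistical structure each stage assumes, so the whole chain
is testable end to end.

```{r, eval = FALSE}
library(amniotime)
co  <- generate_cohort(sim_config(seed = 1))
expr <- remove_batch_effects(co$expression, co$samples$batch,
                             protect = de_design(co$samples$group)[, 2, drop = FALSE])
de  <- differential_expression(expr, co$samples$group)
cv  <- loocv_ttd(expr, co$samples$time_to_delivery, seed = 1)
evaluate_predictions(cv)
```

## The synthetic cohort

The generator draws, per sample, a latent inflammation score `z` with unit
standard deviation, centred at 0 in the later-delivery group and shifted by
`z_shift = 3` in the imminent group (10 of 38 samples by default, mirroring
the motivating study design). Time-to-delivery in weeks is
`max(0.02, 3 - 2 z + e)`, `e ~ N(0, 1.5^2)`, so the imminent group averages
roughly a day and the later group roughly three weeks, with deliveries out
to about two months; the floor encodes that delivery intervals are positive.
A block of 200 response genes (of 2000) gains a per-sample shift
`s_g * (effect_size_log2 / z_shift) * z_i` (signs 60% up / 40% down, so the
expected log2 group difference equals `effect_size_log2 = 1`, i.e. a
two-fold change). Per-gene residual variances are drawn from a scaled
inverse-chi-square distribution with `d0 = 4` and `s0^2 = 0.05` — exactly the
hierarchical model that the empirical-Bayes moderation stage assumes, which
makes its hyperparameters recoverable quantities rather than nuisance
settings. Additive per-gene batch shifts (sd 0.3, two batches) emulate
multi-batch profiling. These defaults are fixed study conditions, not tuning
knobs.

What the generator does *not* emulate: probe-level microarray intensities,
gene-gene correlation beyond the single inflammation axis, heavy-tailed or
missing values, and gestational-age trends in expression. Passing tests
therefore demonstrate correctness of the statistical machinery under the
stated model, not performance on real cohorts; the published performance
figures for this kind of data (Spearman about 0.5, RMSE about 3 weeks,
24-h AUROC about 0.8) come from a real cohort this package cannot
reconstruct, and synthetic results are typically more optimistic because a
single clean latent axis drives both expression and outcome.

## Preprocessing

`remove_batch_effects()` regresses each gene on an intercept, the protected
covariates and sum-to-zero-coded batch indicators, then subtracts only the
fitted batch component. Sum-to-zero coding makes the removed component
average to zero over batches, preserving the grand mean; protecting the
group indicator (the default recommendation — which covariates were
protected is genuinely open, so it is an argument) prevents the correction
from absorbing the biology. The operation is idempotent and refuses
confounded designs. `pca_expression()` takes the singular value
decomposition of the gene-centred (not standardised) matrix over all genes;
variance fractions are squared singular values over their total, and
component signs are arbitrary — downstream checks must be sign-invariant.

## Differential expression

Gene-wise ordinary least squares (`fit_gene_models()`) gives the log2 group
difference `b_g`, residual variance `s_g^2` and shared residual df `d`.
`moderate()` implements the standard empirical-Bayes hierarchical model: the
true variances follow a scaled inverse-chi-square prior `(d0, s0^2)`, under
which `e_g = log s_g^2 - digamma(d/2) + log(d/2)` has mean
`log s0^2 + digamma(d0/2) - log(d0/2)` and excess variance `trigamma(d0/2)`.
The hyperparameters are obtained by moment matching with a Newton inversion
of the trigamma function; posterior variances are the df-weighted average,
and the moderated t has `d0 + d` degrees of freedom. `prior_df = 0` recovers
the ordinary t and `prior_df = Inf` the fully pooled statistic; both limits
are tested numerically, and the estimator is cross-checked against the
reference empirical-Bayes implementation in the test suite.

Calling uses the joint rule of the field: linear fold change strictly
greater than 1.25 *and* Benjamini-Hochberg q strictly below 0.1, with
positive effects meaning up-regulation with imminent delivery. BH ties are
handled by the step-up definition itself (equal p yield equal q). The
adjustment is delegated to `stats::p.adjust` behind the `bh_adjust()`
surface and is verified against a literal step-up evaluation.

## Signatures and enrichment

`define_signatures()` screens a linear-scale reference atlas: a gene is
specific to a tissue when its median there is at least 30 times the median
over all other tissues. Two readings of "all other tissues" are plausible;
the default pools the other tissues' columns, and `compare = "max"` uses the
maximum of their medians (stricter). The boundary is inclusive — a gene at
exactly 30x qualifies — so a zero denominator is replaced by (not augmented
with) a 1e-8 pseudocount, which keeps attained ratios exact. Signatures rank
genes by the specificity ratio (not absolute expression; the alternative is
noted as open) and keep the top 20.

`signature_scores()` standardises each gene against the reference study
group (term deliveries): `Z = (x - mean_ref) / sd_ref`, then averages over
the top 20 available member genes. Reference anchoring (mean score near 0,
unit-ish spread in the reference group) holds by construction. Group
comparison is OLS of the score on the group indicator with BH across
signatures at q < 0.05. `hypergeometric_enrichment()` tests the upper tail
`P(X >= k)` of the overlap between a DE list and each set, with the universe
set to the genes on the matrix (array practice; configurable), BH across
sets at q < 0.05; up- and down-regulated lists should be tested separately.

## Sparse HSIC selection and prediction

The feature selector maximises kernel dependence with the response while
accounting for inter-gene correlation. Each gene's standardised expression
is turned into a Gaussian gram matrix (median-heuristic bandwidth), centred
and Frobenius-normalised; the response's centred gram `Lbar` is regressed on
them under a nonnegative lasso:

`min_{a >= 0} 0.5 || Lbar - sum_g a_g Kbar_g ||_F^2 + lambda ||a||_1`.

Because correlated genes have similar grams, they share weight and the
support stays parsimonious. The solver is projected proximal gradient
(exactly sparse, warm-startable; step size from a power iteration on the
gram-inner-product matrix), and `lambda` is tuned by bisection to the
largest support not exceeding `target_size` (default 50, matching the scale
of the published predictor set). For tractability a marginal screen first
keeps the `screen_size` (default 400) genes with the largest
`<Kbar_g, Lbar>` — marginal HSIC relevance — before the joint fit; genes
outside the screen would enter the lasso with near-zero relevance and are
overwhelmingly pruned anyway. The exact penalty form of the original sparse
HSIC procedure is not public; this HSIC-lasso reading is our codified
choice, documented rather than asserted.

Prediction uses a 1000-tree regression random forest on the selected genes
(package defaults otherwise; per-fold seed = global seed + fold index).
`loocv_ttd()` re-runs *both* selection and forest fitting inside every
leave-one-out fold; the held-out sample never influences selection, and a
contract test corrupts the held-out response to prove it. Metrics are
Spearman correlation, RMSE in weeks, and AUROC for delivery within 24 h
(24/168 weeks exactly), 1 week and 2 weeks, using the negated predicted
time-to-delivery as the risk score and midrank handling of ties (a constant
predictor scores 0.5); a one-class horizon yields `NA`.

Stability across folds is summarised by mean pairwise Jaccard similarity
(defined as 1 when both sets are empty) and mean pairwise Cohen's kappa over
the gene universe — all genes entering selection, the default for the
genuinely open universe question. Consensus genes are those selected more
often than chance: each gene's selection count is tested against
`Binomial(n_folds, p0)` with `p0` the mean fold set size over the universe
size, Bonferroni-corrected across the universe at alpha 0.05 (the correction
choice is itself open; Bonferroni is the conservative reading). Genes
selected in every fold are reported separately.

## Clinical table statistics

Continuous variables: Welch's t from the closed-form statistic and
Satterthwaite df, summarised as median (Q1-Q3) with linear-interpolation
(type-7) quartiles — the interpolation rule is fixed and documented because
published tables rarely state one. Categorical variables: two-sided Fisher's
exact test by point-probability summation (all tables with the observed
margins whose probability is at most the observed one's, within a 1e-7
relative tolerance for floating-point ties) — the convention required to
reproduce standard clinical-table p-values, verified against full
enumeration; denominators shrink to the non-missing counts. Significance is
nominal p < 0.05.

## Numerical choices and degenerate inputs

* Time is in weeks throughout; 24 h = 24/168 weeks exactly.
* Gene identifiers are opaque strings matched exactly across matrix, gene
  sets and atlas; no symbol mapping.
* Constant genes get zero selection weight (their centred grams vanish);
  a constant response empties the selection and the forest falls back to
  the training-mean predictor with a warning.
* A zero reference sd drops the gene from signature scoring with a warning;
  a constant signature score yields p = 1.
* PCA of a constant matrix warns and reports zero variance fractions.
* All generators and the CV loop are deterministic given their seeds.

## Problem sizes in the test suite

The suite exercises the full study scale where it matters — hyperparameter
recovery at 5000 genes x 38 samples, DE operating characteristics on ten
2000-gene cohorts, and one full-scale leave-one-out CV (2000 genes, 1000
trees) — and uses reduced cohorts (200-300 genes, 300 trees, target size 10)
for the 20-seed null-calibration sweep, where the quantity of interest (mean
AUROC under no expression-outcome coupling) does not depend on cohort size.
These sizes are the package's chosen simulation design.

## Limitations

The pipeline starts from a gene-level log2 matrix: probe summarisation,
background correction and normalisation are upstream and out of scope, as
are live gene-ontology services (enrichment takes user-supplied GMT
collections), protein-interaction networks, and any claim of reproducing
cohort-specific published counts. The selector's agreement with the original
sparse HSIC implementation cannot be verified without that code; only the
stated formulation is guaranteed.
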