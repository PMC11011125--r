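# gmbayes

Binary outcome prediction from targeted RNA expression panels with a
**geometric-mean naive Bayesian (GMB) classifier**, stability-based
per-gene selection, and ROC evaluation with Hanley–McNeil confidence
intervals and Youden cut-off scores.

The package is aimed at transplant and hematology groups analysing
targeted bone-marrow transcriptomes (FPKM matrices over a panel of ~1400
cancer-associated genes) to predict acute graft-versus-host disease
(aGvHD) and overall survival after allogeneic stem-cell transplantation —
and, more generally, at anyone classifying a binary endpoint from a small
cohort with many more genes than samples. Because the patient-level data
of such studies are rarely deposited, the package ships a
negative-binomial synthetic-cohort generator with a planted ground truth,
so the entire pipeline is testable end to end.

## The method

Per selected gene $g$, expression $x_g = \log_2(\mathrm{FPKM}_g + 1)$ is
modelled per class $c \in \{0,1\}$ as
$\mathcal{N}(\mu_{gc}, \sigma^2_{gc})$ (sample moments on the training
set; variances floored at $10^{-3}$). Where classical naive Bayes
multiplies the $G$ per-gene likelihoods, GMB takes their **geometric
mean**:

$$\tilde G_c(x) = \exp\Big(\tfrac{1}{G}\textstyle\sum_g \log f(x_g \mid c)\Big),
\qquad
s(x) = \frac{\pi_1 \tilde G_1(x)}{\pi_1 \tilde G_1(x) + \pi_0 \tilde G_0(x)}.$$

The $1/G$ exponent makes the score invariant to duplicating a gene and
comparable across panels of different sizes, and log-space evaluation
keeps scores finite at hundreds of genes with vanishing densities.

Genes enter the model through a rank-based selection stage: a gene is kept
when its Benjamini–Hochberg-adjusted Wilcoxon rank-sum p-value is at most
`alpha` (0.05) **and** it is re-selected in at least a fraction `tau`
(0.6) of B = 100 stratified 80% subsamples (stability selection). The
pipeline splits the cohort 2/3–1/3, selects on training only, produces
out-of-fold GMB scores under stratified 12-fold cross-validation, derives
the Youden cut-off ($\max$ sensitivity + specificity − 1) on training, and
transfers it to the held-out validation set. AUCs are reported with the
Hanley–McNeil standard error
($Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$), a deliberately **unclipped** 95%
Wald interval (so near-perfect AUCs can print upper bounds above 1), and a
two-sided normal p-value against AUC = 0.5.

## Worked example

Simulate a post-transplant-sized cohort (119 samples, 1408 genes, 67%
aGvHD prevalence) with 30 planted outcome-associated genes at a modest
log2 fold-change of 0.8, and run the full pipeline:

```r
library(gmbayes)

cohort <- simulate_cohort(cohort_config(
  n_samples = 119, n_informative = 30, effect_log2fc = 0.8, seed = 7
))
cohort
#> <bm_cohort> 1408 genes x 119 samples (FPKM), 30 informative, prevalence 0.71, seed 7

run <- run_endpoint_analysis(
  cohort$expression, cohort$labels, endpoint = "agvhd",
  config = analysis_config(selection = selection_config(seed = 7), k = 12, seed = 7)
)
run
#> <gmb_run> endpoint agvhd, nested mode, status: ok
#>   panel: 7 genes
#>   training   AUC 0.927 (95% CI 0.871-0.983; p = 2.93e-09), cut-off 0.713
#>   validation AUC 0.926 (95% CI 0.845-1.006; p = 2.44e-05), sens 89.3%, spec 75.0%
```

Reading the output: the selection stage kept a 7-gene panel (at this
effect size only the most discriminative planted genes clear both the
significance and the stability filter); out-of-fold training AUC is 0.927;
on the untouched validation third the model reaches AUC 0.926 — note the
unclipped upper confidence bound of 1.006 — and the training-derived
cut-off of 0.713 operates at 89.3% sensitivity and 75.0% specificity.
The per-gene evidence is a tibble:

```r
head(tibble::as_tibble(run$selection)[order(-run$selection$cv_auc), ], 3)
#> # A tibble: 3 x 6
#>   gene  cv_auc      p_value p_adjusted stability_frequency selected
#>   <chr>  <dbl>        <dbl>      <dbl>               <dbl> <lgl>
#> 1 G0384  0.893 0.0000000489  0.0000689                1    TRUE
#> 2 G0382  0.880 0.000000127   0.0000897                1    TRUE
#> 3 G0728  0.835 0.00000339    0.00159                  1    TRUE
```

`glance(run)` returns the one-row summary, `tidy(run)` the two ROC
summaries, and `autoplot(run)` the overlaid ROC curves. The two published
post-transplant predictor panels (92 genes for aGvHD, 20 for survival) are
bundled as plain-text fixtures: `bundled_panel("agvhd_post")` parses,
normalises (e.g. `"TFRC (CD71)"`, `"43717SEPT9"`) and returns them for use
with `align_panel()` on your own matrices.

## Package layout

- `R/` — synthetic cohort generator, plain-text readers/writers, rank-based
  selection, GMB classifier, ROC evaluation, pipeline orchestration,
  broom-style tidiers and ggplot2 `autoplot()` methods.
- `src/` — compiled kernel for row-wise rank statistics.
- `inst/extdata/` — the 92- and 20-gene panel fixtures.
- `vignettes/gmbayes-methods.Rmd` — the methods vignette: model,
  assumptions, generator calibration, numerical choices, limitations.
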