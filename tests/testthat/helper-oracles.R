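# Shared fixtures and independent oracles used across the suite.

# Exhaustive case-control pair enumeration: the defining form of the
# two-sample AUC, independent of the rank-based implementation under test.
auc_enum <- function(values, labels) {
  y <- as.logical(labels)
  d <- outer(values[y], values[!y], "-")
  (sum(d > 0) + 0.5 * sum(d == 0)) / (sum(y) * sum(!y))
}

# Trapezoidal area under a stored ROC curve (sensitivity vs 1-specificity).
auc_trapezoid <- function(curve) {
  fpr <- 1 - curve$specificity
  sens <- curve$sensitivity
  o <- order(fpr, sens)
  sum(diff(fpr[o]) * (head(sens[o], -1) + tail(sens[o], -1)) / 2)
}

# Small planted-signal cohort used by several tests.
planted_cohort <- function(seed = 1, n_samples = 60, n_genes = 100,
                           n_informative = 8, effect_log2fc = 2.5) {
  simulate_cohort(cohort_config(
    n_samples = n_samples, n_genes = n_genes,
    n_informative = n_informative, effect_log2fc = effect_log2fc,
    seed = seed
  ))
}

quiet_select <- function(...) {
  withCallingHandlers(
    select_genes(...),
    gmb_empty_selection = function(w) invokeRestart("muffleWarning")
  )
}
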