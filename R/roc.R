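# ROC construction, Hanley-McNeil AUC inference and Youden cut-offs.
#
# Conventions (stated and tested): thresholds descend, a score equal to the
# threshold is called positive (>= rule), sentinel thresholds at +Inf and
# -Inf bracket the curve, the AUC is the tie-corrected Mann-Whitney
# probability (identical to the trapezoidal area of the stored curve), and
# the 95% Wald-type confidence interval is deliberately *not* clipped to
# [0, 1].

new_gmb_roc <- function(curve, auc, n_pos, n_neg, se = NA_real_,
                        ci95 = c(NA_real_, NA_real_), p_value = NA_real_,
                        cutoff = NA_real_, sens_at_cutoff = NA_real_,
                        spec_at_cutoff = NA_real_) {
  structure(
    list(
      curve = curve, auc = auc, n_pos = n_pos, n_neg = n_neg,
      se = se, ci95 = ci95, p_value = p_value, cutoff = cutoff,
      sens_at_cutoff = sens_at_cutoff, spec_at_cutoff = spec_at_cutoff
    ),
    class = "gmb_roc"
  )
}

#' @export
print.gmb_roc <- function(x, ...) {
  cat(sprintf(
    "<gmb_roc> AUC %.3f (95%% CI %.3f-%.3f; p = %.3g), n+ = %d, n- = %d\n",
    x$auc, x$ci95[1], x$ci95[2], x$p_value, x$n_pos, x$n_neg
  ))
  if (!is.na(x$cutoff)) {
    cat(sprintf(
      "  cut-off %.3f: sensitivity %.1f%%, specificity %.1f%%\n",
      x$cutoff, 100 * x$sens_at_cutoff, 100 * x$spec_at_cutoff
    ))
  }
  invisible(x)
}

#' Receiver operating characteristic curve
#'
#' Builds the ROC curve of a score against a binary outcome: one threshold
#' per distinct score plus sentinels at `+Inf` and `-Inf`, positivity by the
#' `>=` rule, and the tie-corrected Mann-Whitney AUC (which equals the
#' trapezoidal area of the stored curve).
#'
#' @param scores Finite numeric scores (higher = more case-like).
#' @param labels Binary outcome, same length.
#' @return A `gmb_roc` with the curve and AUC filled; confidence interval,
#'   p-value and cut-off fields are completed by [evaluate_endpoint()].
#' @examples
#' roc_curve(c(.9, .8, .3), c(1, 0, 1))$auc # 0.5
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary(labels)
  check_two_classes(y)
  if (length(scores) != length(y)) stop_domain("scores and labels must align")
  if (anyNA(scores) || any(!is.finite(scores))) stop_domain("scores must be finite")
  n1 <- sum(y)
  n0 <- sum(!y)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  # counts of scores >= t, cumulatively down the sorted distinct values
  pos_at <- vapply(thr, function(t) sum(scores >= t & y), numeric(1))
  neg_at <- vapply(thr, function(t) sum(scores >= t & !y), numeric(1))
  curve <- tibble::tibble(
    threshold = thr,
    sensitivity = pos_at / n1,
    specificity = 1 - neg_at / n0
  )
  r <- rank(scores)
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  new_gmb_roc(curve, auc, n1, n0)
}

#' Hanley-McNeil standard error and 95% interval for an AUC
#'
#' `Q1 = A / (2 - A)`, `Q2 = 2 A^2 / (1 + A)`,
#' `SE = sqrt((A(1-A) + (n+ - 1)(Q1 - A^2) + (n- - 1)(Q2 - A^2)) / (n+ n-))`,
#' and `CI = A +/- 1.96 SE`.  The interval is intentionally not clipped, so
#' upper bounds above 1 (as reported for near-perfect classifiers) are
#' representable.
#'
#' @param auc AUC in `[0, 1]`.
#' @param n_pos,n_neg Positive and negative class counts (>= 1).
#' @return List with elements `se` and `ci95` (length-2 numeric).
#' @examples
#' auc_ci_hanley(0.9, 10, 10)
#' @export
auc_ci_hanley <- function(auc, n_pos, n_neg) {
  if (n_pos < 1 || n_neg < 1) stop_domain("both class counts must be at least 1")
  if (is.na(auc) || auc < 0 || auc > 1) stop_domain("`auc` must lie in [0, 1]")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
    (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  list(se = se, ci95 = auc + c(-1, 1) * qnorm(0.975) * se)
}

#' Two-sided test of AUC = 0.5
#'
#' Normal test of the observed AUC against the chance value 0.5, using the
#' null-hypothesis standard error (the Hanley-McNeil formula evaluated at
#' A = 0.5 with the same class counts).
#'
#' @inheritParams auc_ci_hanley
#' @return p-value in (0, 1].
#' @export
auc_pvalue <- function(auc, n_pos, n_neg) {
  se0 <- auc_ci_hanley(0.5, n_pos, n_neg)$se
  if (se0 == 0) {
    return(if (auc == 0.5) 1 else 0)
  }
  min(1, 2 * pnorm(-abs(auc - 0.5) / se0))
}

#' Youden-optimal cut-off of a ROC curve
#'
#' The threshold maximising `J = sensitivity + specificity - 1`; ties are
#' broken toward the smallest cut-off (favouring sensitivity).  With a
#' completely uninformative score (all values tied) J is 0 everywhere and
#' the `-Inf` sentinel is returned (sensitivity 1, specificity 0).
#'
#' @param roc A `gmb_roc` from [roc_curve()].
#' @return List with `cutoff`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(roc) {
  if (!inherits(roc, "gmb_roc")) stop_domain("`roc` must come from roc_curve()")
  j <- roc$curve$sensitivity + roc$curve$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[length(best)] # thresholds descend: last index = smallest cut-off
  list(
    cutoff = roc$curve$threshold[pick],
    sensitivity = roc$curve$sensitivity[pick],
    specificity = roc$curve$specificity[pick]
  )
}

#' Full ROC evaluation of an endpoint
#'
#' Builds the ROC curve, attaches the Hanley-McNeil standard error, the
#' unclipped 95% confidence interval and the p-value against AUC = 0.5, and
#' reports an operating point: at the Youden-optimal cut-off of these scores
#' when `cutoff` is `NULL` (the training situation), or at a supplied fixed
#' score (a training-derived cut-off applied to validation data).
#'
#' @param scores Numeric scores, or a score-set tibble with a `score`
#'   column (as returned by [cross_validated_scores()] / [apply_model()]).
#' @param labels Binary outcome aligned with the scores.
#' @param cutoff `NULL` to derive the Youden cut-off from these scores, or a
#'   single numeric fixed cut-off.
#' @return A complete `gmb_roc`.
#' @export
evaluate_endpoint <- function(scores, labels, cutoff = NULL) {
  if (is.data.frame(scores)) {
    if (!"score" %in% names(scores)) stop_domain("score-set tibble lacks a `score` column")
    scores <- scores$score
  }
  roc <- roc_curve(scores, labels)
  hm <- auc_ci_hanley(roc$auc, roc$n_pos, roc$n_neg)
  roc$se <- hm$se
  roc$ci95 <- hm$ci95
  roc$p_value <- auc_pvalue(roc$auc, roc$n_pos, roc$n_neg)
  if (is.null(cutoff)) {
    yj <- youden_cutoff(roc)
    roc$cutoff <- yj$cutoff
    roc$sens_at_cutoff <- yj$sensitivity
    roc$spec_at_cutoff <- yj$specificity
  } else {
    if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff)) {
      stop_config("`cutoff` must be NULL or a single numeric score")
    }
    y <- as_binary(labels)
    roc$cutoff <- cutoff
    roc$sens_at_cutoff <- mean(scores[y] >= cutoff)
    roc$spec_at_cutoff <- mean(scores[!y] < cutoff)
  }
  roc
}
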