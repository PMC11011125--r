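# The geometric-mean naive Bayesian (GMB) classifier.
#
# Class-conditional Gaussian densities are fitted per gene on
# log2(FPKM + 1); the class likelihood is the *geometric mean* of the
# per-gene densities (equivalently, the mean of the log-densities), which
# makes the posterior score invariant to duplicating a gene and comparable
# across panels of different sizes — the property that distinguishes GMB
# from the plain product naive Bayes.

#' Fit a geometric-mean naive Bayes model
#'
#' Estimates per-gene, per-class means and variances of `log2(FPKM + 1)`
#' (sample moments, variances clipped from below at `variance_floor`) and
#' class priors.
#'
#' @param x Genes-by-samples FPKM matrix restricted to the model genes.
#' @param labels Binary outcome per sample (0/1 or logical; 1 = class of
#'   interest).
#' @param variance_floor Lower bound for per-gene class variances on the
#'   log2 scale (default 1e-3); prevents infinite densities at constant
#'   genes.
#' @param priors `"empirical"` (training class frequencies, default) or
#'   `"equal"`.
#' @return An object of class `gmb_model`.
#' @seealso [gmb_score()], [apply_model()], [cross_validated_scores()]
#' @export
fit_gmb <- function(x, labels, variance_floor = 1e-3,
                    priors = c("empirical", "equal")) {
  check_expression_matrix(x)
  priors <- match.arg(priors)
  y <- as_binary(labels)
  check_two_classes(y)
  if (ncol(x) != length(y)) stop_domain("labels must match matrix columns")
  if (!is.numeric(variance_floor) || variance_floor <= 0) {
    stop_domain("`variance_floor` must be positive")
  }
  if (min(sum(y), sum(!y)) < 2) {
    stop_domain("each class needs at least 2 training samples to fit variances")
  }
  L <- log2_fpkm(x)
  moments <- function(M) {
    m <- rowMeans(M)
    v <- rowSums((M - m)^2) / (ncol(M) - 1)
    list(mean = m, var = pmax(v, variance_floor))
  }
  m1 <- moments(L[, y, drop = FALSE])
  m0 <- moments(L[, !y, drop = FALSE])
  pi1 <- if (priors == "empirical") mean(y) else 0.5
  structure(
    list(
      genes = rownames(x),
      mean1 = m1$mean, var1 = m1$var,
      mean0 = m0$mean, var0 = m0$var,
      class_priors = c(class0 = 1 - pi1, class1 = pi1),
      variance_floor = variance_floor,
      transform = "log2(FPKM + 1)",
      n_train = c(class0 = sum(!y), class1 = sum(y))
    ),
    class = "gmb_model"
  )
}

#' @export
print.gmb_model <- function(x, ...) {
  cat(sprintf(
    "<gmb_model> %d genes on %s; priors %.3f/%.3f; variance floor %g\n",
    length(x$genes), x$transform, x$class_priors[1], x$class_priors[2],
    x$variance_floor
  ))
  invisible(x)
}

#' Score samples with a GMB model
#'
#' For class c the geometric-mean likelihood is
#' `exp(mean_g log f(x_g | c))` with `f` the Gaussian density at the fitted
#' class parameters, computed in log space throughout; the score is the
#' posterior `pi1 * G1 / (pi1 * G1 + pi0 * G0)`, strictly inside (0, 1).
#' `combine = "product"` instead sums the log-densities — the classical
#' naive Bayes combination, exposed for comparison (it is *not* invariant to
#' gene duplication).
#'
#' @param model A `gmb_model`.
#' @param newdata Genes-by-samples FPKM matrix, or a named vector for a
#'   single sample; must provide a finite value for every model gene.
#' @param combine `"geometric"` (default) or `"product"`.
#' @return Named numeric vector of scores in (0, 1), one per sample.
#' @export
gmb_score <- function(model, newdata, combine = c("geometric", "product")) {
  combine <- match.arg(combine)
  if (!inherits(model, "gmb_model")) stop_domain("`model` must be a gmb_model")
  if (is.null(dim(newdata))) {
    if (is.null(names(newdata))) stop_domain("a single sample must be a named vector")
    newdata <- matrix(newdata,
      ncol = 1,
      dimnames = list(names(newdata), "sample")
    )
  }
  missing <- setdiff(model$genes, rownames(newdata))
  if (length(missing) > 0) {
    stop_domain(sprintf(
      "sample lacks value(s) for model gene(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  L <- log2_fpkm(newdata[model$genes, , drop = FALSE])
  if (any(!is.finite(L))) stop_domain("non-finite expression value supplied for scoring")
  ll1 <- dnorm(L, mean = model$mean1, sd = sqrt(model$var1), log = TRUE)
  ll0 <- dnorm(L, mean = model$mean0, sd = sqrt(model$var0), log = TRUE)
  agg <- if (combine == "geometric") colMeans else colSums
  a1 <- log(model$class_priors["class1"]) + agg(ll1)
  a0 <- log(model$class_priors["class0"]) + agg(ll0)
  stats::setNames(plogis(a1 - a0), colnames(newdata))
}

#' Score an external validation matrix
#'
#' Strictly aligns the matrix to the model genes and scores every sample,
#' tagging the scores with fold `"external"`.
#'
#' @param model A `gmb_model`.
#' @param x Validation genes-by-samples FPKM matrix containing all model
#'   genes.
#' @return A score-set tibble: `sample_id`, `score`, `fold`.
#' @export
apply_model <- function(model, x) {
  if (!inherits(model, "gmb_model")) stop_domain("`model` must be a gmb_model")
  if (ncol(x) == 0) {
    return(tibble::tibble(
      sample_id = character(), score = numeric(), fold = character()
    ))
  }
  aligned <- align_panel(x, model$genes, policy = "strict")
  tibble::tibble(
    sample_id = colnames(aligned),
    score = unname(gmb_score(model, aligned)),
    fold = "external"
  )
}

#' Out-of-fold GMB scores under stratified k-fold cross-validation
#'
#' Partitions the samples into k stratified folds (seeded) and scores each
#' fold with a model fitted on the other k - 1.  In `"nested"` mode (no
#' selection leakage) gene selection is re-run inside every training
#' portion; in `"paper"` mode one selection computed on the full cohort
#' supplied here is reused for every fold, mirroring pipelines that select
#' before cross-validating (expect optimistic in-training performance).
#'
#' @param x Genes-by-samples FPKM matrix.
#' @param labels Binary outcome per sample.
#' @param selection_config A [selection_config()] for the per-fold (or
#'   one-shot) gene selection.
#' @param k Number of folds (default 12); must not exceed the smaller class
#'   count.
#' @param mode `"nested"` (default) or `"paper"`.
#' @param seed Seed for the fold assignment.
#' @param variance_floor,priors Passed to [fit_gmb()].
#' @param fallback_top If the selection is empty (as it should be under a
#'   global null), use the top `fallback_top` genes by cross-validated AUC
#'   instead; `NULL` (default) errors in that situation.
#' @return A score-set tibble: `sample_id`, `score`, `fold` (integer as
#'   character), `label`; every sample scored exactly once out-of-fold.
#' @export
cross_validated_scores <- function(x, labels,
                                   selection_config = selection_config(),
                                   k = 12L,
                                   mode = c("nested", "paper"),
                                   seed = 1L,
                                   variance_floor = 1e-3,
                                   priors = c("empirical", "equal"),
                                   fallback_top = NULL) {
  mode <- match.arg(mode)
  priors <- match.arg(priors)
  check_expression_matrix(x)
  y <- as_binary(labels)
  check_two_classes(y)
  if (ncol(x) != length(y)) stop_domain("labels must match matrix columns")
  fold <- stratified_folds(y, k, derive_seed(seed, 11L))
  shared_panel <- NULL
  if (mode == "paper") {
    shared_panel <- selection_panel(x, y, selection_config, fallback_top)
  }
  out <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    panel <- shared_panel %||%
      selection_panel(x[, tr, drop = FALSE], y[tr], selection_config, fallback_top)
    model <- fit_gmb(x[panel, tr, drop = FALSE], y[tr],
      variance_floor = variance_floor, priors = priors
    )
    test <- which(!tr)
    out[[f]] <- tibble::tibble(
      sample_id = colnames(x)[test],
      score = unname(gmb_score(model, x[panel, test, drop = FALSE])),
      fold = f,
      label = as.integer(y[test])
    )
  }
  scores <- dplyr::bind_rows(out)
  scores[match(colnames(x), scores$sample_id), ]
}

# Shared helper: run selection, fall back to the top-N ranked genes when the
# selection is empty and a fallback size was requested.
selection_panel <- function(x, y, config, fallback_top) {
  report <- withCallingHandlers(
    select_genes(x, y, config),
    gmb_empty_selection = function(w) invokeRestart("muffleWarning")
  )
  panel <- selected_genes(report)
  if (length(panel) == 0) {
    if (is.null(fallback_top)) {
      stop_domain(paste(
        "no genes met the selection criteria;",
        "set `fallback_top` to score with a top-ranked fallback panel"
      ))
    }
    panel <- head(rank_report_genes(report), fallback_top)
  }
  panel
}
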