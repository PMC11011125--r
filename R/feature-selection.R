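# Per-gene rank statistics, stability selection and the SelectionReport.

# Pure-R row-wise mid-ranks + tie correction for a genes-by-samples matrix:
# a single radix sort over the flattened matrix instead of a per-gene rank()
# loop.  Retained as the reference implementation that the compiled kernel
# (src/rank_stats.cpp) is tested against.
row_rank_stats <- function(X) {
  G <- nrow(X)
  N <- ncol(X)
  n <- G * N
  ri <- rep_len(seq_len(G), n) # row index in column-major order
  xv <- as.vector(X)
  o <- order(ri, xv)
  sv <- xv[o]
  rown <- ri[o]
  pos <- rep(seq_len(N), G)
  newrun <- c(TRUE, sv[-1] != sv[-n] | rown[-1] != rown[-n])
  runid <- cumsum(newrun)
  runlen <- tabulate(runid)
  mid <- (rowsum(pos, runid)[, 1] / runlen)[runid]
  r <- numeric(n)
  r[o] <- mid
  tie3 <- rowsum(runlen^3 - runlen, rown[newrun])[, 1]
  list(ranks = matrix(r, G, N), tie3 = tie3)
}

# Row-wise two-sample Mann-Whitney statistics.  Returns, per gene, the raw
# AUC (P(case > control) + 0.5 P(tie)), the orientation-folded AUC, and a
# two-sided rank-sum p-value: exact (tie-free, total n <= 30) or normal
# approximation with tie and continuity correction, mirroring
# stats::wilcox.test conventions.
row_rank_tests <- function(X, y) {
  y <- as_binary(y)
  check_two_classes(y)
  if (ncol(X) != length(y)) stop_domain("labels must match matrix columns")
  n1 <- sum(y)
  n0 <- sum(!y)
  N <- n1 + n0
  rs <- row_rank_stats_cpp(X, y)
  R1 <- rs$R1
  U1 <- R1 - n1 * (n1 + 1) / 2
  auc_raw <- U1 / (n1 * n0)
  mu <- n1 * n0 / 2
  sig2 <- n1 * n0 / 12 * ((N + 1) - rs$tie3 / (N * (N - 1)))
  z <- U1 - mu
  zc <- (z - sign(z) * 0.5) / sqrt(pmax(sig2, .Machine$double.eps))
  p <- ifelse(sig2 <= 0, 1, pmin(1, 2 * pnorm(-abs(zc))))
  exact <- rs$tie3 == 0 & N <= 30
  if (any(exact)) {
    Ue <- U1[exact]
    pe <- ifelse(
      Ue > mu,
      2 * pwilcox(Ue - 1, n1, n0, lower.tail = FALSE),
      2 * pwilcox(Ue, n1, n0)
    )
    p[exact] <- pmin(1, pe)
  }
  list(auc_raw = auc_raw, auc = pmax(auc_raw, 1 - auc_raw), p = p)
}

#' Single-gene discriminative performance (two-sample AUC)
#'
#' The tie-corrected Mann-Whitney probability
#' `(#concordant + 0.5 #ties) / (n_pos * n_neg)`, folded to
#' `max(A, 1 - A)` so down- and up-regulated genes score symmetrically.
#'
#' @param values Expression values of one gene across samples.
#' @param labels Binary outcome (0/1 or logical), same length.
#' @return AUC in `[0.5, 1]`.
#' @examples
#' per_gene_auc(c(3, 5, 1, 4), c(1, 1, 0, 0)) # 0.75
#' @export
per_gene_auc <- function(values, labels) {
  if (anyNA(values) || any(!is.finite(values))) stop_domain("`values` must be finite")
  row_rank_tests(matrix(values, nrow = 1), labels)$auc
}

#' Single-gene two-sided Wilcoxon rank-sum test
#'
#' Exact p-value when the sample is tie-free with at most 30 observations,
#' otherwise the normal approximation with tie and continuity correction.
#' Degenerate all-tied samples give p = 1.
#'
#' @inheritParams per_gene_auc
#' @return p-value in (0, 1].
#' @examples
#' per_gene_test(c(10, 12, 14, 1, 2, 3), c(1, 1, 1, 0, 0, 0)) # exact: 0.1
#' @export
per_gene_test <- function(values, labels) {
  if (anyNA(values) || any(!is.finite(values))) stop_domain("`values` must be finite")
  row_rank_tests(matrix(values, nrow = 1), labels)$p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]) with
#' domain validation: inputs must lie in (0, 1].
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p_values) {
  if (length(p_values) == 0) {
    return(numeric())
  }
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    stop_domain("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Configuration for stability-based gene selection
#'
#' @param n_resamples Number of stability subsample replicates B
#'   (default 100).
#' @param subsample_fraction Fraction of each class drawn (without
#'   replacement, stratified) per replicate, in (0, 1] (default 0.8).
#' @param cv_folds_inner Folds of the inner cross-validation used for the
#'   per-gene cross-validated AUC (default 5).
#' @param alpha Significance level applied to BH-adjusted p-values
#'   (default 0.05).
#' @param stability_threshold Minimum selection frequency tau across
#'   replicates, in (0, 1] (default 0.6).
#' @param max_genes Optional cap: keep at most this many selected genes,
#'   ranked by cross-validated AUC (ties by smaller adjusted p, then symbol).
#' @param seed Seed for the subsampling and inner-fold streams.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(n_resamples = 100L,
                             subsample_fraction = 0.8,
                             cv_folds_inner = 5L,
                             alpha = 0.05,
                             stability_threshold = 0.6,
                             max_genes = NULL,
                             seed = 1L) {
  if (!is.numeric(n_resamples) || length(n_resamples) != 1 || n_resamples < 1 ||
    n_resamples != round(n_resamples)) {
    stop_config("`n_resamples` must be a positive integer")
  }
  if (!is.numeric(subsample_fraction) || length(subsample_fraction) != 1 ||
    subsample_fraction <= 0 || subsample_fraction > 1) {
    stop_config("`subsample_fraction` must lie in (0, 1]")
  }
  if (!is.numeric(cv_folds_inner) || length(cv_folds_inner) != 1 ||
    cv_folds_inner < 2 || cv_folds_inner != round(cv_folds_inner)) {
    stop_config("`cv_folds_inner` must be an integer >= 2")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop_config("`alpha` must lie in (0, 1)")
  }
  if (!is.numeric(stability_threshold) || length(stability_threshold) != 1 ||
    stability_threshold <= 0 || stability_threshold > 1) {
    stop_config("`stability_threshold` must lie in (0, 1]")
  }
  if (!is.null(max_genes) &&
    (!is.numeric(max_genes) || length(max_genes) != 1 || max_genes < 1 ||
      max_genes != round(max_genes))) {
    stop_config("`max_genes` must be NULL or a positive integer")
  }
  structure(
    list(
      n_resamples = as.integer(n_resamples),
      subsample_fraction = subsample_fraction,
      cv_folds_inner = as.integer(cv_folds_inner),
      alpha = alpha,
      stability_threshold = stability_threshold,
      max_genes = if (is.null(max_genes)) NULL else as.integer(max_genes),
      seed = as.integer(seed)
    ),
    class = "selection_config"
  )
}

# Per-gene cross-validated AUC: orientation (up/down in cases) is learned on
# each inner-training portion and applied to the held-out samples; the pooled
# out-of-fold oriented values are then scored against the labels.  Under the
# null this is centred at 0.5 (unlike the folded in-sample AUC).
cv_gene_auc <- function(X, y, folds_inner, seed) {
  y <- as_binary(y)
  k <- min(folds_inner, sum(y), sum(!y))
  fold <- stratified_folds(y, k, seed)
  S <- matrix(NA_real_, nrow(X), ncol(X))
  for (f in seq_len(k)) {
    tr <- fold != f
    orient <- ifelse(row_rank_tests(X[, tr, drop = FALSE], y[tr])$auc_raw >= 0.5, 1, -1)
    S[, !tr] <- X[, !tr, drop = FALSE] * orient
  }
  row_rank_tests(S, y)$auc_raw
}

#' Per-gene stability frequencies
#'
#' For each of B seeded stratified subsamples (fraction
#' `subsample_fraction` of each class, without replacement), a gene scores a
#' hit when its BH-adjusted rank-sum p-value on the subsample is at most
#' `alpha`.  The frequency is hits/B; granularity is exactly 1/B.  A
#' replicate whose subsample loses a class is re-drawn (at most 10 attempts).
#'
#' @param x Genes-by-samples expression matrix.
#' @param labels Binary outcome per sample.
#' @param config A [selection_config()].
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
stability_frequencies <- function(x, labels, config = selection_config()) {
  check_expression_matrix(x)
  y <- as_binary(labels)
  check_two_classes(y)
  if (!inherits(config, "selection_config")) {
    stop_config("`config` must be created with selection_config()")
  }
  hits <- numeric(nrow(x))
  for (b in seq_len(config$n_resamples)) {
    idx <- NULL
    for (attempt in 1:10) {
      cand <- stratified_subsample(
        y, config$subsample_fraction,
        derive_seed(config$seed, 1000L + b * 17L + attempt)
      )
      if (any(y[cand]) && any(!y[cand])) {
        idx <- cand
        break
      }
    }
    if (is.null(idx)) stop_domain("subsampling left a class empty in 10 consecutive draws")
    p_adj <- adjust_pvalues(row_rank_tests(x[, idx, drop = FALSE], y[idx])$p)
    hits <- hits + (p_adj <= config$alpha)
  }
  stats::setNames(hits / config$n_resamples, rownames(x))
}

#' Stability-based per-gene selection
#'
#' The gene-selection stage of the pipeline: each gene is scored by its
#' cross-validated single-gene AUC, tested with a two-sided Wilcoxon
#' rank-sum test (BH-adjusted across the panel), and measured for stability
#' as its selection frequency over B stratified subsamples.  A gene is
#' selected when its adjusted p-value is at most `alpha` *and* its stability
#' frequency is at least `stability_threshold`; `max_genes`, if set,
#' truncates the selection to the top genes by cross-validated AUC (ties
#' broken by smaller adjusted p, then symbol).
#'
#' @inheritParams stability_frequencies
#' @return A `selection_report`: tibble with one row per gene and columns
#'   `gene`, `cv_auc`, `p_value`, `p_adjusted`, `stability_frequency`,
#'   `selected`, carrying attributes `selected_genes` (ordered) and
#'   `config`.  An empty selection is returned with a warning, not an error.
#' @examples
#' cohort <- simulate_cohort(cohort_config(
#'   n_samples = 60, n_genes = 80,
#'   n_informative = 8, effect_log2fc = 2.5, seed = 42
#' ))
#' rep <- select_genes(cohort$expression, cohort$labels$agvhd,
#'   selection_config(n_resamples = 20)
#' )
#' sum(rep$selected)
#' @export
select_genes <- function(x, labels, config = selection_config()) {
  check_expression_matrix(x)
  y <- as_binary(labels)
  check_two_classes(y)
  if (!inherits(config, "selection_config")) {
    stop_config("`config` must be created with selection_config()")
  }
  tests <- row_rank_tests(x, y)
  cv_auc <- cv_gene_auc(x, y, config$cv_folds_inner, derive_seed(config$seed, 77L))
  p_adj <- adjust_pvalues(tests$p)
  stab <- stability_frequencies(x, y, config)
  selected <- p_adj <= config$alpha & stab >= config$stability_threshold
  report <- tibble::tibble(
    gene = rownames(x),
    cv_auc = cv_auc,
    p_value = tests$p,
    p_adjusted = p_adj,
    stability_frequency = unname(stab),
    selected = selected
  )
  ord <- order(-report$cv_auc, report$p_adjusted, report$gene)
  ranked_selected <- report$gene[ord][report$selected[ord]]
  if (!is.null(config$max_genes) && length(ranked_selected) > config$max_genes) {
    ranked_selected <- ranked_selected[seq_len(config$max_genes)]
    report$selected <- report$gene %in% ranked_selected
  }
  if (length(ranked_selected) == 0) {
    rlang::warn("no genes met the significance and stability criteria",
      class = "gmb_empty_selection"
    )
  }
  structure(report,
    selected_genes = ranked_selected,
    config = config,
    class = c("selection_report", class(report))
  )
}

#' Selected genes of a selection report
#'
#' @param report A `selection_report` from [select_genes()].
#' @return Character vector of selected genes, ranked by cross-validated AUC.
#' @export
selected_genes <- function(report) {
  if (!inherits(report, "selection_report")) {
    stop_domain("`report` must be a selection_report")
  }
  attr(report, "selected_genes")
}

# Ranking used for selection order and fallback panels: best cross-validated
# AUC first, ties by smaller adjusted p, then symbol.
rank_report_genes <- function(report) {
  report$gene[order(-report$cv_auc, report$p_adjusted, report$gene)]
}
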