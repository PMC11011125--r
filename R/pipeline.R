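# End-to-end analysis: split -> select (training only) -> cross-validated
# training scores -> training ROC with Youden cut-off -> final model ->
# external validation ROC at the training cut-off.

#' Split a cohort into training and validation sets
#'
#' Draws a seeded random split with training fraction `fraction` (default
#' 2/3).  The global training size is `round(fraction * n)`; when
#' stratified, per-stratum sizes are set by largest-remainder rounding so
#' class proportions in the two sets differ by at most one sample's worth.
#'
#' @param labels Label tibble with `sample_id` and the endpoint column.
#' @param endpoint Column used for stratification (`"agvhd"` maps to the
#'   `agvhd` column, `"survival"` to `alive`).
#' @param fraction Training fraction in (0, 1), default 2/3.
#' @param stratify Stratify on the endpoint (default TRUE).
#' @param seed Seed for the assignment.
#' @return A tibble `sample_id`, `set` (`"training"`/`"validation"`) with
#'   attributes `seed` and `stratified`.
#' @examples
#' labs <- tibble::tibble(sample_id = sprintf("s%02d", 1:12), agvhd = rep(0:1, 6))
#' table(split_cohort(labs, seed = 3)$set)
#' @export
split_cohort <- function(labels, endpoint = c("agvhd", "survival"),
                         fraction = 2 / 3, stratify = TRUE, seed = 1L) {
  endpoint <- match.arg(endpoint)
  column <- endpoint_column(endpoint)
  if (!is.data.frame(labels) || !all(c("sample_id", column) %in% names(labels))) {
    stop_domain(sprintf("`labels` must contain `sample_id` and `%s`", column))
  }
  n <- nrow(labels)
  if (n < 3) stop_domain("need at least 3 samples to split")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop_config("`fraction` must lie strictly inside (0, 1)")
  }
  y <- as_binary(labels[[column]], column)
  n_train <- round(fraction * n)
  train_idx <- if (stratify) {
    check_two_classes(y, column)
    if (min(sum(y), sum(!y)) < 2) {
      stop_config(paste(
        "a class has a single sample; stratified splitting is degenerate --",
        "use `stratify = FALSE`"
      ))
    }
    strata <- list(which(y), which(!y))
    ideal <- vapply(strata, length, numeric(1)) * fraction
    base <- floor(ideal)
    remainder <- ideal - base
    extra <- n_train - sum(base)
    take <- base + (rank(-remainder, ties.method = "first") <= extra)
    withr::with_seed(seed, {
      unlist(Map(function(idx, m) safe_sample(idx, m), strata, take))
    })
  } else {
    withr::with_seed(seed, safe_sample(seq_len(n), n_train))
  }
  assignment <- tibble::tibble(
    sample_id = labels$sample_id,
    set = ifelse(seq_len(n) %in% train_idx, "training", "validation")
  )
  attr(assignment, "seed") <- seed
  attr(assignment, "stratified") <- stratify
  assignment
}

endpoint_column <- function(endpoint) {
  switch(endpoint,
    agvhd = "agvhd",
    survival = "alive",
    stop_config(sprintf("unknown endpoint '%s'", endpoint))
  )
}

#' Configuration for an end-to-end endpoint analysis
#'
#' @param selection A [selection_config()] for the gene-selection stage.
#' @param k Cross-validation folds for the training score set (default 12).
#' @param cv_mode `"nested"` (selection re-run inside each fold; default) or
#'   `"paper"` (one selection on the full training cohort reused across
#'   folds — optimistic, kept reproducible on purpose).
#' @param variance_floor,priors Passed to [fit_gmb()].
#' @param split_fraction Training fraction of the cohort split
#'   (default 2/3).
#' @param stratify Stratify the split on the endpoint (default TRUE).
#' @param cutoff_source `"training"` (Youden cut-off derived on training
#'   scores and transferred to validation; default) or `"validation"`
#'   (derived on the validation scores themselves).
#' @param fallback_top Optional fallback panel size when the selection is
#'   empty (see [cross_validated_scores()]).
#' @param seed Master seed; split, selection and folds use derived streams.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(selection = selection_config(),
                            k = 12L,
                            cv_mode = c("nested", "paper"),
                            variance_floor = 1e-3,
                            priors = c("empirical", "equal"),
                            split_fraction = 2 / 3,
                            stratify = TRUE,
                            cutoff_source = c("training", "validation"),
                            fallback_top = NULL,
                            seed = 1L) {
  if (!inherits(selection, "selection_config")) {
    stop_config("`selection` must be created with selection_config()")
  }
  structure(
    list(
      selection = selection,
      k = as.integer(k),
      cv_mode = match.arg(cv_mode),
      variance_floor = variance_floor,
      priors = match.arg(priors),
      split_fraction = split_fraction,
      stratify = stratify,
      cutoff_source = match.arg(cutoff_source),
      fallback_top = if (is.null(fallback_top)) NULL else as.integer(fallback_top),
      seed = as.integer(seed)
    ),
    class = "analysis_config"
  )
}

#' Run the full analysis for one endpoint
#'
#' Executes the complete pipeline on one cohort: seeded 2/3-1/3 split,
#' stability-based gene selection on the training set only, out-of-fold GMB
#' scores under stratified k-fold cross-validation of the training set,
#' training ROC with Youden cut-off, a final model fitted on the full
#' training set, external scoring of the validation set, and the validation
#' ROC evaluated at the training-derived cut-off.  Validation samples are
#' quarantined after the split: they influence no selection, fitting or
#' cut-off choice.
#'
#' @param x Genes-by-samples FPKM matrix for the whole cohort.
#' @param labels Label tibble (`sample_id`, `agvhd`, `alive`, ...) aligned
#'   with the matrix columns.
#' @param endpoint `"agvhd"` or `"survival"`.
#' @param config An [analysis_config()].
#' @param split Optional precomputed [split_cohort()] assignment (to hold
#'   the partition fixed across runs).
#' @return A `gmb_run`: list with the selection report, panel, split,
#'   training/validation score sets and `gmb_roc` objects, the final model,
#'   config echo, seed and package version.  If no gene is selected and no
#'   fallback is configured, a structured result with
#'   `status = "no_informative_genes"` is returned instead of an error.
#' @export
run_endpoint_analysis <- function(x, labels,
                                  endpoint = c("agvhd", "survival"),
                                  config = analysis_config(),
                                  split = NULL) {
  endpoint <- match.arg(endpoint)
  if (!inherits(config, "analysis_config")) {
    stop_config("`config` must be created with analysis_config()")
  }
  check_expression_matrix(x)
  column <- endpoint_column(endpoint)
  if (!all(colnames(x) %in% labels$sample_id)) {
    stop_domain("every matrix sample needs a row in `labels`")
  }
  labels <- labels[match(colnames(x), labels$sample_id), ]
  y <- as_binary(labels[[column]], column)

  split <- split %||% split_cohort(labels,
    endpoint = endpoint, fraction = config$split_fraction,
    stratify = config$stratify, seed = derive_seed(config$seed, 21L)
  )
  set_of <- split$set[match(colnames(x), split$sample_id)]
  tr <- set_of == "training"
  if (!any(y[tr]) || all(y[tr]) || !any(y[!tr]) || all(y[!tr])) {
    stop_domain("both classes must be present in both split halves")
  }
  x_train <- x[, tr, drop = FALSE]
  y_train <- y[tr]
  x_valid <- x[, !tr, drop = FALSE]
  y_valid <- y[!tr]

  sel_config <- config$selection
  sel_config$seed <- derive_seed(config$seed, 22L)
  selection <- withCallingHandlers(
    select_genes(x_train, y_train, sel_config),
    gmb_empty_selection = function(w) invokeRestart("muffleWarning")
  )
  panel <- selected_genes(selection)
  used_fallback <- FALSE
  if (length(panel) == 0) {
    if (is.null(config$fallback_top)) {
      return(new_gmb_run(
        endpoint = endpoint, status = "no_informative_genes",
        selection = selection, split = split, config = config
      ))
    }
    panel <- head(rank_report_genes(selection), config$fallback_top)
    used_fallback <- TRUE
  }

  scores_train <- cross_validated_scores(
    x_train, y_train,
    selection_config = sel_config, k = config$k, mode = config$cv_mode,
    seed = derive_seed(config$seed, 23L),
    variance_floor = config$variance_floor, priors = config$priors,
    fallback_top = config$fallback_top
  )
  roc_train <- evaluate_endpoint(scores_train, y_train, cutoff = NULL)

  model <- fit_gmb(x_train[panel, , drop = FALSE], y_train,
    variance_floor = config$variance_floor, priors = config$priors
  )
  scores_valid <- apply_model(model, x_valid)
  scores_valid$label <- as.integer(y_valid)
  roc_valid <- evaluate_endpoint(
    scores_valid, y_valid,
    cutoff = if (config$cutoff_source == "training") roc_train$cutoff else NULL
  )

  new_gmb_run(
    endpoint = endpoint, status = "ok", selection = selection,
    panel = panel, used_fallback = used_fallback, split = split,
    scores_training = scores_train, scores_validation = scores_valid,
    roc_training = roc_train, roc_validation = roc_valid,
    model = model, config = config
  )
}

new_gmb_run <- function(endpoint, status, selection, split, config,
                        panel = character(), used_fallback = FALSE,
                        scores_training = NULL, scores_validation = NULL,
                        roc_training = NULL, roc_validation = NULL,
                        model = NULL) {
  structure(
    list(
      endpoint = endpoint,
      status = status,
      mode = config$cv_mode,
      selection = selection,
      panel = panel,
      used_fallback = used_fallback,
      split = split,
      scores_training = scores_training,
      scores_validation = scores_validation,
      roc_training = roc_training,
      roc_validation = roc_validation,
      model = model,
      config = config,
      seed = config$seed,
      version = as.character(packageVersion("gmbayes"))
    ),
    class = "gmb_run"
  )
}

#' @export
print.gmb_run <- function(x, ...) {
  cat(sprintf("<gmb_run> endpoint %s, %s mode, status: %s\n", x$endpoint, x$mode, x$status))
  if (x$status == "ok") {
    cat(sprintf(
      "  panel: %d genes%s\n", length(x$panel),
      if (x$used_fallback) " (fallback ranking)" else ""
    ))
    cat(sprintf(
      "  training   AUC %.3f (95%% CI %.3f-%.3f; p = %.3g), cut-off %.3f\n",
      x$roc_training$auc, x$roc_training$ci95[1], x$roc_training$ci95[2],
      x$roc_training$p_value, x$roc_training$cutoff
    ))
    cat(sprintf(
      "  validation AUC %.3f (95%% CI %.3f-%.3f; p = %.3g), sens %.1f%%, spec %.1f%%\n",
      x$roc_validation$auc, x$roc_validation$ci95[1], x$roc_validation$ci95[2],
      x$roc_validation$p_value, 100 * x$roc_validation$sens_at_cutoff,
      100 * x$roc_validation$spec_at_cutoff
    ))
  }
  invisible(x)
}

#' Run all four endpoint analyses
#'
#' Repeats [run_endpoint_analysis()] for every available timepoint cohort
#' (`pre`, `post`) and endpoint (`agvhd`, `survival`), with independent
#' split/selection seeds per analysis.  A missing timepoint is skipped with
#' a warning.
#'
#' @param matrices Named list of genes-by-samples matrices, names among
#'   `"pre"`, `"post"`.
#' @param labels Named list of label tibbles matching `matrices`.
#' @param config An [analysis_config()]; its seed is the master seed from
#'   which each analysis derives its own.
#' @return A `gmb_run_set`: list of `gmb_run` objects named
#'   `<timepoint>_<endpoint>` plus a `summary` tibble (one [glance()] row
#'   per completed analysis).
#' @export
run_all <- function(matrices, labels, config = analysis_config()) {
  if (!is.list(matrices) || is.null(names(matrices))) {
    stop_config("`matrices` must be a named list with names among 'pre'/'post'")
  }
  runs <- list()
  key <- 0L
  for (tp in c("pre", "post")) {
    for (endpoint in c("agvhd", "survival")) {
      key <- key + 100L
      if (is.null(matrices[[tp]])) {
        rlang::warn(sprintf("no %s-transplant matrix supplied; skipping %s/%s", tp, tp, endpoint))
        next
      }
      cfg <- config
      cfg$seed <- derive_seed(config$seed, key)
      runs[[paste(tp, endpoint, sep = "_")]] <-
        run_endpoint_analysis(matrices[[tp]], labels[[tp]], endpoint, cfg)
    }
  }
  summary <- dplyr::bind_rows(lapply(names(runs), function(nm) {
    g <- glance(runs[[nm]])
    tibble::add_column(g, analysis = nm, .before = 1)
  }))
  structure(list(runs = runs, summary = summary), class = "gmb_run_set")
}

#' @export
print.gmb_run_set <- function(x, ...) {
  cat(sprintf("<gmb_run_set> %d analyses\n", length(x$runs)))
  print(x$summary)
  invisible(x)
}
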