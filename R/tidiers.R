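# broom-style tidiers for the package's result objects.

#' Tidy a GMB model
#'
#' One row per gene and class with the fitted Gaussian parameters of
#' `log2(FPKM + 1)`.
#'
#' @param x A `gmb_model`.
#' @param ... Unused.
#' @return Tibble `gene`, `class`, `mean`, `variance`.
#' @method tidy gmb_model
#' @export
tidy.gmb_model <- function(x, ...) {
  tibble::tibble(
    gene = rep(x$genes, 2),
    class = rep(c(0L, 1L), each = length(x$genes)),
    mean = c(unname(x$mean0), unname(x$mean1)),
    variance = c(unname(x$var0), unname(x$var1))
  )
}

#' @rdname tidy.gmb_model
#' @return `glance()` returns a one-row tibble with the panel size, priors,
#'   variance floor and training class counts.
#' @method glance gmb_model
#' @export
glance.gmb_model <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes),
    prior_class1 = unname(x$class_priors["class1"]),
    variance_floor = x$variance_floor,
    n_train_class1 = unname(x$n_train["class1"]),
    n_train_class0 = unname(x$n_train["class0"]),
    transform = x$transform
  )
}

#' Tidy a ROC result
#'
#' @param x A `gmb_roc`.
#' @param ... Unused.
#' @return `tidy()` returns the curve tibble (`threshold`, `sensitivity`,
#'   `specificity`); `glance()` a one-row summary with AUC, Hanley-McNeil
#'   SE, the unclipped 95% CI, p-value and the operating point.
#' @method tidy gmb_roc
#' @export
tidy.gmb_roc <- function(x, ...) {
  x$curve
}

#' @rdname tidy.gmb_roc
#' @method glance gmb_roc
#' @export
glance.gmb_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, se = x$se,
    ci_low = x$ci95[1], ci_high = x$ci95[2],
    p_value = x$p_value,
    cutoff = x$cutoff,
    sensitivity = x$sens_at_cutoff,
    specificity = x$spec_at_cutoff,
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' Tidy a pipeline run
#'
#' @param x A `gmb_run`.
#' @param ... Unused.
#' @return `tidy()` returns one row per evaluation set with the full ROC
#'   summary; `glance()` a one-row overview of the run.
#' @method tidy gmb_run
#' @export
tidy.gmb_run <- function(x, ...) {
  if (x$status != "ok") {
    return(tibble::tibble(set = character()))
  }
  dplyr::bind_rows(
    tibble::add_column(glance(x$roc_training), set = "training", .before = 1),
    tibble::add_column(glance(x$roc_validation), set = "validation", .before = 1)
  )
}

#' @rdname tidy.gmb_run
#' @method glance gmb_run
#' @export
glance.gmb_run <- function(x, ...) {
  if (x$status != "ok") {
    return(tibble::tibble(
      endpoint = x$endpoint, mode = x$mode, status = x$status,
      n_genes = 0L
    ))
  }
  tibble::tibble(
    endpoint = x$endpoint,
    mode = x$mode,
    status = x$status,
    n_genes = length(x$panel),
    auc_training = x$roc_training$auc,
    auc_validation = x$roc_validation$auc,
    cutoff = x$roc_validation$cutoff,
    sens_validation = x$roc_validation$sens_at_cutoff,
    spec_validation = x$roc_validation$spec_at_cutoff,
    p_validation = x$roc_validation$p_value
  )
}

#' @rdname select_genes
#' @param x A `selection_report`.
#' @param ... Unused.
#' @method glance selection_report
#' @export
glance.selection_report <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_selected = sum(x$selected),
    min_p_adjusted = min(x$p_adjusted),
    max_stability = max(x$stability_frequency)
  )
}
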