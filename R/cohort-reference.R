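#' Reference cohort composition for generator calibration
#'
#' Published single-centre allogeneic-HSCT cohort counts to which the
#' synthetic-cohort defaults are calibrated: number of profiled patients per
#' timepoint cohort, number diagnosed with acute graft-versus-host disease
#' (aGvHD, any stage), and number alive at analysis.  The `"all"` row counts
#' every profiled patient; `"pre"` and `"post"` count patients with a
#' pre-transplant or post-transplant bone-marrow sample respectively (a
#' patient can appear in both).
#'
#' @return A tibble with columns `cohort`, `n_samples`, `n_agvhd`, `n_alive`
#'   (`n_alive` is `NA` where not reported per cohort).
#' @examples
#' hsct_cohort_composition()
#' @export
hsct_cohort_composition <- function() {
  tibble::tibble(
    cohort    = c("all", "pre", "post"),
    n_samples = c(167L, 132L, 119L),
    n_agvhd   = c(109L, 87L, 80L),
    n_alive   = c(108L, NA_integer_, 87L)
  )
}

#' Endpoint prevalence in the reference cohort
#'
#' Proportion of patients with the event (aGvHD of any stage, or alive at
#' analysis for the survival endpoint) in the reference cohort composition,
#' used as the default case prevalence of the synthetic generator.
#'
#' @param endpoint `"agvhd"` or `"survival"`.
#' @param cohort `"post"` (default), `"pre"` or `"all"`.
#' @return A proportion in (0, 1).
#' @examples
#' endpoint_prevalence("agvhd", "post") # 80/119
#' @export
endpoint_prevalence <- function(endpoint = c("agvhd", "survival"),
                                cohort = c("post", "pre", "all")) {
  endpoint <- match.arg(endpoint)
  cohort <- match.arg(cohort)
  ref <- hsct_cohort_composition()
  row <- ref[ref$cohort == cohort, ]
  num <- if (endpoint == "agvhd") row$n_agvhd else row$n_alive
  if (is.na(num)) {
    stop_domain(sprintf("%s prevalence is not recorded for the '%s' cohort", endpoint, cohort))
  }
  num / row$n_samples
}
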