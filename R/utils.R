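# Internal helpers shared across modules.

# Counter-derived sub-seed: one master seed, independent streams per stage so
# adding a stage never perturbs draws made by earlier stages.  Kept < 2^31.
derive_seed <- function(seed, key) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 7919 + as.numeric(key) * 104729 + 1) %% 2147483587)
}

stop_config <- function(message, ...) rlang::abort(message, class = "gmb_config_error", ...)
stop_format <- function(message, ...) rlang::abort(message, class = "gmb_format_error", ...)
stop_domain <- function(message, ...) rlang::abort(message, class = "gmb_domain_error", ...)

# The global expression transform used by every Gaussian-model step.
log2_fpkm <- function(x) log2(x + 1)

as_binary <- function(labels, arg = "labels") {
  if (is.logical(labels)) {
    if (anyNA(labels)) stop_domain(sprintf("`%s` contains missing values", arg))
    return(labels)
  }
  if (is.numeric(labels) && !anyNA(labels) && all(labels %in% c(0, 1))) {
    return(labels == 1)
  }
  stop_domain(sprintf("`%s` must be binary (0/1 or logical) without missing values", arg))
}

check_two_classes <- function(y, arg = "labels") {
  if (!any(y) || all(y)) {
    stop_domain(sprintf("`%s` must contain both classes", arg))
  }
  invisible(y)
}

# sample() without the length-1 surprise
safe_sample <- function(x, size) x[sample.int(length(x), size)]

# Stratified fold assignment: within each class, a seeded shuffle then
# round-robin fold labels, so fold class counts differ by at most one.
stratified_folds <- function(y, k, seed) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop_config("`k` must be an integer >= 2")
  smallest <- min(sum(y), sum(!y))
  if (k > smallest) {
    stop_config(sprintf(
      "`k` = %d exceeds the smaller class count (%d); choose k <= %d",
      k, smallest, smallest
    ))
  }
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in c(TRUE, FALSE)) {
      idx <- safe_sample(which(y == cl), sum(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Stratified subsample of column indices (used by stability selection).
stratified_subsample <- function(y, fraction, seed) {
  withr::with_seed(seed, {
    sort(c(
      safe_sample(which(y), max(1L, ceiling(fraction * sum(y)))),
      safe_sample(which(!y), max(1L, ceiling(fraction * sum(!y))))
    ))
  })
}

check_expression_matrix <- function(x, arg = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_domain(sprintf("`%s` must be a numeric genes-by-samples matrix", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_domain(sprintf("`%s` must carry gene row names and sample column names", arg))
  }
  if (anyDuplicated(rownames(x))) stop_format("duplicate gene identifiers in matrix")
  if (anyDuplicated(colnames(x))) stop_format("duplicate sample identifiers in matrix")
  if (any(!is.finite(x))) stop_domain(sprintf("`%s` contains non-finite values", arg))
  if (any(x < 0)) stop_domain(sprintf("`%s` contains negative values", arg))
  invisible(x)
}
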