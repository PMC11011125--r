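test_that("ROC worked cases: perfect, all-tied, and mixed scores", {
  perfect <- roc_curve(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(perfect$auc, 1)
  # the curve passes through (fpr, tpr) = (0, 1)
  expect_true(any(perfect$curve$sensitivity == 1 & perfect$curve$specificity == 1))

  tied <- roc_curve(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(tied$auc, 0.5)

  mixed <- roc_curve(c(0.9, 0.8, 0.3), c(1, 0, 1))
  expect_equal(mixed$auc, 0.5) # one concordant, one discordant pair

  expect_error(roc_curve(1:4, rep(1, 4)), class = "gmb_domain_error")
})

test_that("curve conventions hold: descending thresholds, sentinels, monotone arrays", {
  set.seed(42)
  s <- round(runif(30), 2)
  y <- rbinom(30, 1, 0.5)
  y[1:2] <- c(0, 1)
  roc <- roc_curve(s, y)
  thr <- roc$curve$threshold
  expect_equal(thr[1], Inf)
  expect_equal(thr[length(thr)], -Inf)
  expect_true(all(diff(thr) < 0))
  expect_true(all(diff(roc$curve$sensitivity) >= 0)) # rises as threshold falls
  expect_true(all(diff(1 - roc$curve$specificity) >= 0))
})

test_that("AUC equals both pair enumeration and the trapezoidal curve area", {
  set.seed(9)
  for (i in 1:250) {
    n <- sample(4:12, 1)
    y <- integer(n)
    while (sum(y) %in% c(0, n)) y <- rbinom(n, 1, 0.5)
    s <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    roc <- roc_curve(s, y)
    expect_equal(roc$auc, auc_enum(s, y))
    expect_equal(roc$auc, auc_trapezoid(roc$curve), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone score transforms and reverses under negation", {
  set.seed(13)
  s <- rnorm(40)
  y <- rbinom(40, 1, 0.5)
  y[1:2] <- c(0, 1)
  a <- roc_curve(s, y)$auc
  expect_equal(roc_curve(exp(s), y)$auc, a)
  expect_equal(roc_curve(-s, y)$auc, 1 - a)
})

test_that("cross-check against an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  s <- sample(seq(0, 1, 0.1), 80, replace = TRUE)
  y <- rbinom(80, 1, 0.6)
  y[1:2] <- c(0, 1)
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  ours <- roc_curve(s, y)$auc
  expect_equal(max(ours, 1 - ours), max(ref, 1 - ref), tolerance = 1e-12)
})

test_that("Hanley-McNeil closed forms: degenerate, algebraic, and hand-evaluated cases", {
  perfect <- auc_ci_hanley(1, 12, 30)
  expect_equal(perfect$se, 0)
  expect_equal(perfect$ci95, c(1, 1))

  # algebraic identities at A = 0.5: Q1 = Q2 = 1/3, so both variance
  # contributions are (Q - A^2) = 1/12 and the SE collapses to the exact
  # Mann-Whitney null standard deviation sqrt((N + 1) / (12 n+ n-))
  expect_equal(0.5 / (2 - 0.5), 1 / 3)
  expect_equal(2 * 0.5^2 / (1 + 0.5), 1 / 3)
  half <- auc_ci_hanley(0.5, 20, 20)
  expect_equal(half$se, sqrt(41 / (12 * 400)))

  # hand substitution at A = 0.9, 10 vs 10
  q1 <- 0.9 / 1.1
  q2 <- 2 * 0.81 / 1.9
  se_hand <- sqrt((0.09 + 9 * (q1 - 0.81) + 9 * (q2 - 0.81)) / 100)
  got <- auc_ci_hanley(0.9, 10, 10)
  expect_equal(got$se, se_hand)
  expect_gt(got$ci95[2], 1) # deliberately unclipped
})

test_that("confidence-interval width shrinks at a root-n rate at fixed AUC", {
  w <- function(n) diff(auc_ci_hanley(0.8, n, n)$ci95)
  expect_equal(w(50) / w(200), 2, tolerance = 0.05)
  expect_equal(w(200) / w(800), 2, tolerance = 0.05)
})

test_that("the AUC p-value uses the null SE and behaves monotonically", {
  expect_equal(auc_pvalue(0.5, 15, 25), 1)
  # hand evaluation: the null SE at 20 vs 20 is the exact Mann-Whitney null
  # SD sqrt(41/4800) ~= 0.0924, so A = 0.75 gives z ~= 2.705
  expect_equal(auc_pvalue(0.75, 20, 20), 2 * pnorm(-0.25 / sqrt(41 / 4800)))
  ps <- vapply(seq(0.5, 0.95, 0.05), auc_pvalue, numeric(1), n_pos = 15, n_neg = 15)
  expect_true(all(diff(ps) < 0))
})

test_that("Youden cut-offs maximise J with the smallest-cutoff tie-break", {
  sep <- evaluate_endpoint(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(sep$cutoff, 0.8) # smallest distinct score achieving J = 1
  expect_equal(sep$sens_at_cutoff, 1)
  expect_equal(sep$spec_at_cutoff, 1)

  tied <- evaluate_endpoint(rep(0.3, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(tied$cutoff, -Inf) # J = 0 everywhere: the sentinel wins
  expect_equal(tied$sens_at_cutoff, 1)
  expect_equal(tied$spec_at_cutoff, 0)

  ex <- roc_curve(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1))
  yj <- youden_cutoff(ex)
  expect_equal(yj$cutoff, 0.6)
  expect_equal(yj$sensitivity, 1)
  expect_equal(yj$specificity, 1)
})

test_that("fixed cut-offs reproduce the transferred operating point", {
  s <- c(0.2, 0.4, 0.6, 0.8)
  y <- c(0, 1, 0, 1)
  low <- evaluate_endpoint(s, y, cutoff = 0.05)
  expect_equal(low$sens_at_cutoff, 1)
  expect_equal(low$spec_at_cutoff, 0)

  at <- evaluate_endpoint(s, y, cutoff = 0.4) # >= rule: 0.4 counts positive
  expect_equal(at$sens_at_cutoff, 1)
  expect_equal(at$spec_at_cutoff, 0.5)

  # a training set evaluated at its own Youden cut-off realises max J
  set.seed(21)
  s2 <- runif(50)
  y2 <- rbinom(50, 1, plogis(4 * (s2 - 0.5)))
  y2[1:2] <- c(0, 1)
  own <- evaluate_endpoint(s2, y2)
  j_all <- own$curve$sensitivity + own$curve$specificity - 1
  expect_equal(own$sens_at_cutoff + own$spec_at_cutoff - 1, max(j_all))

  expect_error(evaluate_endpoint(s, y, cutoff = "training"), class = "gmb_config_error")
})
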