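test_that("per-gene AUC matches its defining worked cases", {
  expect_equal(per_gene_auc(c(10, 11, 12, 1, 2), c(1, 1, 1, 0, 0)), 1)
  expect_equal(per_gene_auc(rep(3, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(per_gene_auc(c(3, 5, 1, 4), c(1, 1, 0, 0)), 0.75)
  # orientation folding: a strongly down-regulated gene scores the same
  expect_equal(
    per_gene_auc(c(1, 2, 10, 11), c(1, 1, 0, 0)),
    per_gene_auc(c(10, 11, 1, 2), c(1, 1, 0, 0))
  )
  expect_error(per_gene_auc(1:4, c(1, 1, 1, 1)), class = "gmb_domain_error")
})

test_that("per-gene AUC equals exhaustive pair enumeration on random small instances", {
  set.seed(71)
  for (i in 1:300) {
    n <- sample(4:12, 1)
    y <- integer(n)
    while (sum(y) %in% c(0, n)) y <- rbinom(n, 1, 0.5)
    v <- sample(1:5, n, replace = TRUE) + 0 # heavy ties on purpose
    a <- auc_enum(v, y)
    expect_equal(per_gene_auc(v, y), max(a, 1 - a))
  }
})

test_that("per-gene rank-sum p-values match the exact and approximate conventions", {
  # perfect separation of 3 vs 3: exact two-sided tail is 2/20
  expect_equal(per_gene_test(c(10, 12, 14, 1, 2, 3), c(1, 1, 1, 0, 0, 0)), 0.1)
  # degenerate all-tied sample
  expect_equal(per_gene_test(rep(7, 8), rep(c(1, 0), 4)), 1)

  # dual route: stats::wilcox.test is the oracle in both regimes
  set.seed(5)
  for (i in 1:40) {
    n <- sample(6:20, 1)
    y <- integer(n)
    while (min(sum(y), n - sum(y)) < 3) y <- rbinom(n, 1, 0.5)
    v <- rnorm(n) # tie-free -> exact branch
    ref <- stats::wilcox.test(v[y == 1], v[y == 0], exact = TRUE)$p.value
    expect_equal(per_gene_test(v, y), ref)
  }
  for (i in 1:40) {
    n <- sample(31:80, 1)
    y <- integer(n)
    while (min(sum(y), n - sum(y)) < 5) y <- rbinom(n, 1, 0.5)
    v <- sample(1:12, n, replace = TRUE) + 0 # ties -> normal approximation
    ref <- suppressWarnings(
      stats::wilcox.test(v[y == 1], v[y == 0], exact = FALSE, correct = TRUE)$p.value
    )
    expect_equal(per_gene_test(v, y), ref)
  }
})

test_that("the compiled rank kernel agrees with the pure-R reference", {
  set.seed(31)
  X <- matrix(sample(1:25, 400 * 37, replace = TRUE) + 0, 400)
  y <- rep_len(c(TRUE, TRUE, FALSE), 37)
  cpp <- gmbayes:::row_rank_stats_cpp(X, y)
  ref <- gmbayes:::row_rank_stats(X)
  expect_equal(cpp$R1, as.numeric(ref$ranks %*% y))
  expect_equal(cpp$tie3, unname(ref$tie3))
})

test_that("BH adjustment follows the step-up worked cases and validates its domain", {
  expect_equal(adjust_pvalues(0.037), 0.037)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.8, 0.04)
  adj <- adjust_pvalues(p)
  expect_true(all(adj >= p))
  expect_equal(order(adj), order(p)) # step-up preserves ordering here
  expect_error(adjust_pvalues(c(0.5, 0)), class = "gmb_domain_error")
  expect_error(adjust_pvalues(c(0.5, 1.2)), class = "gmb_domain_error")
})

test_that("stability frequencies have 1/B granularity and are seed-reproducible", {
  co <- planted_cohort(seed = 6, n_samples = 50, n_genes = 60, n_informative = 5)
  y <- co$labels$agvhd

  one <- stability_frequencies(co$expression, y, selection_config(n_resamples = 1))
  expect_true(all(one %in% c(0, 1)))

  cfg <- selection_config(n_resamples = 7, seed = 3)
  f1 <- stability_frequencies(co$expression, y, cfg)
  f2 <- stability_frequencies(co$expression, y, cfg)
  expect_identical(f1, f2)
  expect_true(all(abs(f1 * 7 - round(f1 * 7)) < 1e-12))
})

test_that("genes with very large planted effects are perfectly stable", {
  co <- simulate_cohort(cohort_config(
    n_samples = 200, n_genes = 150,
    n_informative = 10, effect_log2fc = 3, seed = 17
  ))
  freq <- stability_frequencies(
    co$expression, co$labels$agvhd,
    selection_config(n_resamples = 20, seed = 2)
  )
  expect_equal(unname(freq[co$truth$informative_genes]), rep(1, 10))
})

test_that("selection is invariant to strictly monotone per-gene transforms", {
  co <- planted_cohort(seed = 12, n_samples = 60, n_genes = 80)
  cfg <- selection_config(n_resamples = 15, seed = 4)
  a <- quiet_select(co$expression, co$labels$agvhd, cfg)
  b <- quiet_select(sqrt(co$expression), co$labels$agvhd, cfg)
  expect_equal(a$cv_auc, b$cv_auc)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$stability_frequency, b$stability_frequency)
  expect_identical(a$selected, b$selected)
})

test_that("select_genes enforces the joint significance-and-stability rule", {
  co <- planted_cohort(seed = 8, n_samples = 80, n_genes = 120, n_informative = 12)
  cfg <- selection_config(n_resamples = 25, seed = 5)
  rep <- quiet_select(co$expression, co$labels$agvhd, cfg)
  expect_equal(nrow(rep), 120)
  sel <- rep[rep$selected, ]
  expect_true(all(sel$p_adjusted <= cfg$alpha))
  expect_true(all(sel$stability_frequency >= cfg$stability_threshold))
  expect_setequal(selected_genes(rep), sel$gene)

  capped <- quiet_select(
    co$expression, co$labels$agvhd,
    selection_config(n_resamples = 25, seed = 5, max_genes = 3)
  )
  expect_lte(sum(capped$selected), 3)
  expect_equal(
    selected_genes(capped),
    head(selected_genes(rep), length(selected_genes(capped)))
  )
})

test_that("under the global null almost nothing is selected", {
  fracs <- vapply(1:8, function(s) {
    co <- simulate_cohort(cohort_config(n_samples = 80, n_genes = 300, seed = 100 + s))
    rep <- quiet_select(
      co$expression, co$labels$agvhd,
      selection_config(n_resamples = 15, seed = s)
    )
    mean(rep$selected)
  }, numeric(1))
  expect_lte(mean(fracs), 0.01)
})

test_that("an empty selection warns rather than errors", {
  co <- simulate_cohort(cohort_config(n_samples = 40, n_genes = 50, seed = 77))
  expect_warning(
    select_genes(co$expression, co$labels$agvhd, selection_config(n_resamples = 5)),
    class = "gmb_empty_selection"
  )
})
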