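test_that("fitted moments equal an independent recomputation", {
  co <- planted_cohort(seed = 4, n_samples = 40, n_genes = 12)
  y <- co$labels$agvhd == 1
  model <- fit_gmb(co$expression, co$labels$agvhd)

  # second, independent route to the same moments
  L <- log2(co$expression + 1)
  for (g in rownames(co$expression)) {
    expect_equal(unname(model$mean1[g]), mean(L[g, y]))
    expect_equal(unname(model$mean0[g]), mean(L[g, !y]))
    expect_equal(unname(model$var1[g]), max(stats::var(L[g, y]), model$variance_floor))
    expect_equal(unname(model$var0[g]), max(stats::var(L[g, !y]), model$variance_floor))
  }
  expect_equal(unname(model$class_priors["class1"]), mean(y))
  expect_equal(sum(model$class_priors), 1)

  equal <- fit_gmb(co$expression, co$labels$agvhd, priors = "equal")
  expect_equal(unname(equal$class_priors), c(0.5, 0.5))
})

test_that("constant genes hit the variance floor exactly and classes need 2 samples", {
  x <- rbind(
    FLAT = rep(8, 10),
    VAR1 = c(1:5, 11:15)
  )
  colnames(x) <- sprintf("s%02d", 1:10)
  y <- rep(c(1, 0), each = 5)
  model <- fit_gmb(x, y, variance_floor = 1e-3)
  expect_equal(unname(model$var1["FLAT"]), 1e-3)
  expect_equal(unname(model$var0["FLAT"]), 1e-3)
  expect_gt(unname(model$var1["VAR1"]), 1e-3)

  expect_error(fit_gmb(x[, 1:6], c(1, 1, 1, 1, 1, 0)), class = "gmb_domain_error")
})

test_that("the single-gene score matches direct normal-density evaluation", {
  # class 1 ~ N(2, 1), class 0 ~ N(0, 1) on the log2 scale, equal priors;
  # observing x at the class-1 mean gives d1/(d1+d0) ~= 0.881
  model <- structure(
    list(
      genes = "G1",
      mean1 = c(G1 = 2), var1 = c(G1 = 1),
      mean0 = c(G1 = 0), var0 = c(G1 = 1),
      class_priors = c(class0 = 0.5, class1 = 0.5),
      variance_floor = 1e-3, transform = "log2(FPKM + 1)",
      n_train = c(class0 = 10, class1 = 10)
    ),
    class = "gmb_model"
  )
  x <- c(G1 = 2^2 - 1) # log2(x + 1) = 2
  d1 <- stats::dnorm(2, 2, 1)
  d0 <- stats::dnorm(2, 0, 1)
  expect_equal(unname(gmb_score(model, x)), d1 / (d1 + d0), tolerance = 1e-12)
  expect_equal(unname(gmb_score(model, x)), 0.881, tolerance = 1e-3)

  # equidistant observation under equal priors scores exactly 0.5
  mid <- c(G1 = 2^1 - 1)
  expect_equal(unname(gmb_score(model, mid)), 0.5)
})

test_that("the geometric mean is duplication-invariant and the plain product is not", {
  co <- planted_cohort(seed = 10, n_samples = 50, n_genes = 6, n_informative = 3)
  model <- fit_gmb(co$expression, co$labels$agvhd)
  sample1 <- co$expression[, 7]

  dup <- rbind(co$expression, co$expression)
  rownames(dup) <- c(rownames(co$expression), paste0(rownames(co$expression), "_B"))
  dup_model <- fit_gmb(dup, co$labels$agvhd)
  dup_sample <- c(sample1, stats::setNames(sample1, paste0(names(sample1), "_B")))

  gmb_once <- unname(gmb_score(model, sample1))
  gmb_twice <- unname(gmb_score(dup_model, dup_sample))
  expect_equal(gmb_twice, gmb_once, tolerance = 1e-12)

  nb_once <- unname(gmb_score(model, sample1, combine = "product"))
  nb_twice <- unname(gmb_score(dup_model, dup_sample, combine = "product"))
  expect_false(isTRUE(all.equal(nb_twice, nb_once, tolerance = 1e-6)))
})

test_that("scores stay finite and non-degenerate for 1000 genes with tiny densities", {
  g <- sprintf("G%04d", 1:1000)
  model <- structure(
    list(
      genes = g,
      mean1 = stats::setNames(rep(0.2, 1000), g), var1 = stats::setNames(rep(1, 1000), g),
      mean0 = stats::setNames(rep(0, 1000), g), var0 = stats::setNames(rep(1, 1000), g),
      class_priors = c(class0 = 0.5, class1 = 0.5),
      variance_floor = 1e-3, transform = "log2(FPKM + 1)",
      n_train = c(class0 = 10, class1 = 10)
    ),
    class = "gmb_model"
  )
  # observations ~40 SD from both means: per-gene densities < 1e-300
  x <- stats::setNames(rep(2^40 - 1, 1000), g)
  s <- unname(gmb_score(model, x))
  expect_true(is.finite(s))
  expect_gt(s, 0)
  expect_lt(s, 1)
})

test_that("moving one gene toward the class-1 mean never lowers the score (equal variances)", {
  g <- c("A", "B", "C")
  model <- structure(
    list(
      genes = g,
      mean1 = stats::setNames(c(3, 1, 2), g), var1 = stats::setNames(rep(0.5, 3), g),
      mean0 = stats::setNames(c(1, 2, 2), g), var0 = stats::setNames(rep(0.5, 3), g),
      class_priors = c(class0 = 0.4, class1 = 0.6),
      variance_floor = 1e-3, transform = "log2(FPKM + 1)",
      n_train = c(class0 = 10, class1 = 10)
    ),
    class = "gmb_model"
  )
  base <- c(A = 0.5, B = 3, C = 2)
  path <- seq(0.5, 3, length.out = 25) # walk gene A toward its class-1 mean
  scores <- vapply(path, function(v) {
    x <- 2^c(A = v, B = 3, C = 2) - 1
    unname(gmb_score(model, x))
  }, numeric(1))
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("fitted class means converge to the generating means at a root-n rate", {
  err_at <- function(n, seed) {
    co <- simulate_cohort(cohort_config(
      n_samples = n, n_genes = 40, n_informative = 10,
      effect_log2fc = 1, seed = seed
    ))
    big <- simulate_cohort(cohort_config(
      n_samples = 6400, n_genes = 40, n_informative = 10,
      effect_log2fc = 1, seed = seed
    ))
    m <- fit_gmb(co$expression, co$labels$agvhd)
    truth <- fit_gmb(big$expression, big$labels$agvhd)
    mean(abs(c(m$mean1 - truth$mean1, m$mean0 - truth$mean0)))
  }
  errs <- vapply(c(50, 200, 800), function(n) {
    mean(vapply(1:3, function(s) err_at(n, 300 + s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0)) # monotone decrease
  # 16-fold more data should shrink the error roughly 4-fold
  expect_gt(errs[1] / errs[3], 2)
})

test_that("cross-validated scores partition the cohort and are reproducible", {
  co <- planted_cohort(seed = 14, n_samples = 60, n_genes = 80)
  y <- co$labels$agvhd
  cfg <- selection_config(n_resamples = 10, seed = 2)
  s1 <- cross_validated_scores(co$expression, y, cfg, k = 5, seed = 9, fallback_top = 10)
  s2 <- cross_validated_scores(co$expression, y, cfg, k = 5, seed = 9, fallback_top = 10)
  expect_identical(s1, s2)
  expect_setequal(s1$sample_id, colnames(co$expression))
  expect_equal(anyDuplicated(s1$sample_id), 0L)
  expect_setequal(unique(s1$fold), 1:5)
  expect_true(all(s1$score > 0 & s1$score < 1))

  expect_error(
    cross_validated_scores(co$expression, y, cfg, k = 50, seed = 1),
    "choose k", class = "gmb_config_error"
  )
})

test_that("paper-mode cross-validation is optimistic on planted signal", {
  co <- simulate_cohort(cohort_config(
    n_samples = 80, n_genes = 150,
    n_informative = 15, effect_log2fc = 2, seed = 19
  ))
  y <- co$labels$agvhd
  sc <- cross_validated_scores(
    co$expression, y, selection_config(n_resamples = 20, seed = 1),
    k = 8, mode = "paper", seed = 3
  )
  expect_gte(evaluate_endpoint(sc, y)$auc, 0.9)
})

test_that("apply_model scores externally, strictly, and handles empty input", {
  co <- planted_cohort(seed = 16, n_samples = 40, n_genes = 10, n_informative = 5)
  model <- fit_gmb(co$expression, co$labels$agvhd)

  # a sample sitting at the class-1 density mode scores above 0.5 (equal priors)
  eq <- fit_gmb(co$expression, co$labels$agvhd, priors = "equal")
  proto <- matrix(2^eq$mean1 - 1,
    ncol = 1,
    dimnames = list(eq$genes, "proto")
  )
  expect_gt(apply_model(eq, proto)$score, 0.5)

  got <- apply_model(model, co$expression[, 1:4])
  expect_equal(got$fold, rep("external", 4))
  expect_equal(got$sample_id, colnames(co$expression)[1:4])

  empty <- apply_model(model, co$expression[, 0])
  expect_equal(nrow(empty), 0)

  expect_error(apply_model(model, co$expression[1:3, ]),
    model$genes[4],
    class = "gmb_domain_error"
  )
})
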