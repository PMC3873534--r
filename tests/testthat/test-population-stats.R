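test_that("dip statistic matches closed-form values on anchor cases", {
  # equally spaced samples: 1/(2n) for any n
  expect_equal(dip_statistic(1:10), 1 / 20)
  expect_equal(dip_statistic(seq(0, 3, by = 1)), 1 / 8)
  # any three distinct points: 1/6, regardless of spacing
  expect_equal(dip_statistic(c(0, 1, 100)), 1 / 6)
  expect_equal(dip_statistic(c(0, 1)), 1 / 4)
  # two point masses p / (1-p): min(p, 1-p) / 2
  expect_equal(dip_statistic(rep(c(0, 1), each = 50)), 0.25)
  expect_equal(dip_statistic(rep(c(0, 1), c(30, 70))), 0.15)
  expect_equal(dip_statistic(rep(c(0, 1), c(10, 90))), 0.05)
  # three equal masses: same as 3 distinct points
  expect_equal(dip_statistic(rep(c(0, 1, 2), each = 10)), 1 / 6)
  # a single value is exactly unimodal
  expect_equal(dip_statistic(rep(5, 20)), 0)
})

test_that("dip statistic is affine invariant and properly bounded", {
  set.seed(11)
  for (i in 1:5) {
    x <- stats::rnorm(80)
    d <- dip_statistic(x)
    expect_equal(dip_statistic(3.7 * x - 12), d)
    expect_gte(d, 1 / 160)
    expect_lte(d, 0.25)
  }
})

test_that("dip test requires at least four observations", {
  expect_error(dip_test(c(1, 2, 3)), "at least 4")
})

test_that("well-separated bimodal samples are detected by the dip test", {
  set.seed(12)
  x <- c(stats::rnorm(111, 0.6, 0.1), stats::rnorm(111, 15, 1))
  expect_lt(dip_test(x, n_reference = 2000)$p_value, 0.01)
})

test_that("AIC-stopped mixture selects one component for one Gaussian", {
  k <- vapply(1:10, function(s) {
    set.seed(400 + s)
    fit_gmm_aic(stats::rnorm(200, 5, 2))$n_components
  }, 0L)
  expect_gte(mean(k == 1L), 0.9)
})

test_that("mixture fit invariants: weights, assignments, error cases", {
  set.seed(13)
  x <- c(stats::rnorm(100, 0, 1), stats::rnorm(100, 10, 1))
  f <- fit_gmm_aic(x)
  expect_equal(sum(f$weights), 1, tolerance = 1e-6)
  expect_length(f$assignments, length(x))
  expect_true(all(f$assignments %in% seq_len(f$n_components)))
  expect_true(all(f$sds > 0))
  expect_true(all(diff(f$means) > 0))
  expect_error(fit_gmm_aic(1:5), "at least 8")
  # infinite values are excluded before fitting
  f2 <- fit_gmm_aic(c(x, Inf, Inf))
  expect_equal(f2$n, length(x))
})

test_that("rate classification splits at 2 sp/s with the boundary fast", {
  expect_equal(classify_rates(c(0.6, 15.0)), c("slow", "fast"))
  expect_equal(classify_rates(2.0), "fast")
  expect_equal(classify_rates(numeric()), character())
})

test_that("binomial test matches direct tail summation and printed counts", {
  for (cse in list(c(3, 20), c(0, 15), c(10, 50), c(2, 30))) {
    expect_equal(binomial_fraction_test(cse[1], cse[2], 0.05)$p_value,
                 brute_binom_p(cse[1], cse[2], 0.05), tolerance = 1e-9)
  }
  expect_lt(binomial_fraction_test(417, 813, 0.05)$p_value, 1e-15)
  expect_gt(binomial_fraction_test(41, 813, 0.05)$p_value, 0.05)
  expect_error(binomial_fraction_test(0, 0), "n_pairs")
})

test_that("Fisher enrichment equals hypergeometric enumeration", {
  pairs <- data.frame(unit_a = rep(c("f1", "s1"), each = 10),
                      unit_b = rep(c("f2", "s2"), each = 10),
                      significant = rep(c(TRUE, FALSE), each = 10),
                      stringsAsFactors = FALSE)
  classes <- c(f1 = "fast", f2 = "fast", s1 = "slow", s2 = "slow")
  res <- fast_pair_enrichment(pairs, classes)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  # all pairs significant: degenerate margin
  pairs$significant <- TRUE
  expect_error(fast_pair_enrichment(pairs, classes), "degenerate margin")
})

test_that("synchrony independent of class passes the Fisher screen", {
  ps <- vapply(1:20, function(s) {
    set.seed(700 + s)
    n <- 200
    cls <- sample(c("fast", "slow"), 2 * n, replace = TRUE)
    names(cls) <- paste0("u", seq_len(2 * n))
    pairs <- data.frame(unit_a = paste0("u", seq_len(n)),
                        unit_b = paste0("u", n + seq_len(n)),
                        significant = stats::runif(n) < 0.3,
                        stringsAsFactors = FALSE)
    fast_pair_enrichment(pairs, cls)$p_value
  }, 0)
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("heterogeneity chi-square flags extreme between-group splits", {
  pairs <- data.frame(
    patient_id = rep(paste0("P", 1:5), each = 20),
    epoch_id = "e1",
    significant = rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), each = 20))
  res <- heterogeneity_test(pairs, pairs$patient_id)
  expect_lt(res$p_value, 1e-6)
  expect_error(heterogeneity_test(pairs[1:20, ], rep("P1", 20)),
               "at least 2 groups")
})

test_that("null heterogeneity p-values are approximately uniform", {
  ps <- vapply(1:200, function(s) {
    set.seed(900 + s)
    pairs <- data.frame(patient_id = rep(paste0("P", 1:6), each = 25),
                        significant = stats::runif(150) < 0.4)
    heterogeneity_test(pairs, pairs$patient_id)$p_value
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("anesthesia screen recovers an injected +11 sp/s effect", {
  set.seed(14)
  n <- 200
  cov <- data.frame(drug = sample(c(TRUE, FALSE), n, replace = TRUE),
                    temp = stats::rnorm(n, 36.3, 0.5))
  rates <- 5 + 11 * cov$drug + stats::rnorm(n, 0, 5)
  rep_ <- anesthesia_glm(rates, cov)
  row <- rep_$table[rep_$table$variable == "drug", ]
  expect_lt(abs(row$effect_estimate - 11), 2)
  expect_true(row$significant_after_fdr)
  expect_error(anesthesia_glm(rates[1:5], cov[1:5, ]), "at least 10")
})

test_that("constant covariates are skipped with a note", {
  set.seed(15)
  cov <- data.frame(flat = rep(1, 50), x = stats::rnorm(50))
  rep_ <- anesthesia_glm(stats::rnorm(50, 10, 2), cov)
  expect_equal(rep_$skipped, "flat")
  expect_false("flat" %in% rep_$table$variable)
})

test_that("BH at q = 0.2 never rejects fewer hypotheses than Bonferroni", {
  set.seed(16)
  for (i in 1:20) {
    p <- stats::runif(8)^sample(c(1, 3), 8, replace = TRUE)
    bh <- sum(stats::p.adjust(p, "BH") <= 0.2)
    bonf <- sum(stats::p.adjust(p, "bonferroni") <= 0.2)
    expect_gte(bh, bonf)
  }
})

test_that("residual rate distribution keeps its two classes after the GLM", {
  hits <- vapply(1:6, function(s) {
    set.seed(1700 + s)
    n <- 222
    cls <- stats::runif(n) < 0.45
    rates <- ifelse(cls, stats::rnorm(n, 0.6, 0.35),
                    stats::rnorm(n, 15, 5))
    cov <- data.frame(drug = sample(c(TRUE, FALSE), n, replace = TRUE),
                      temp = stats::rnorm(n, 36.3, 0.5))
    rates <- rates + 1.5 * cov$drug
    rep_ <- anesthesia_glm(rates, cov)
    residual_multimodality(rep_, n_reference = 500)$p_value < 0.05
  }, TRUE)
  expect_gt(mean(hits), 0.5)
  # a single-class sample typically stays unimodal in the residuals
  set.seed(18)
  rep1 <- anesthesia_glm(stats::rnorm(222, 10, 3),
                         data.frame(x = stats::rnorm(222)))
  expect_gt(residual_multimodality(rep1, n_reference = 500)$p_value, 0.05)
})
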