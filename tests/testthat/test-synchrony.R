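test_that("bin_counts uses half-open bins with boundary to the later bin", {
  bin <- 1 / 1024
  expect_length(bin_counts(numeric(), 0, 2, bin), 2048L)
  centers <- (seq_len(2048) - 0.5) * bin
  expect_equal(bin_counts(centers, 0, 2, bin), rep(1L, 2048))
  # a spike exactly on a bin boundary belongs to the later bin
  expect_equal(which(bin_counts(10 * bin, 0, 2, bin) == 1L), 11L)
  expect_equal(sum(bin_counts(c(0, 0.5, 1.999, 2.0), 0, 2, bin)), 3L)
})

test_that("spectral averaged CCG equals brute-force lagged pair counting", {
  p <- ccg_params(max_lag_ms = 10)
  for (s in 1:4) {
    a <- generate_poisson_train(15, 6, seed = 100 + s)
    b <- generate_poisson_train(10, 6, seed = 200 + s)
    r <- averaged_ccg(a, b, 6, p)
    maxlag <- (length(r$delays) - 1) / 2
    bf <- brute_ccg(a, b, 6, p$segment_s, p$bin_s, maxlag)
    expect_equal(r$values, bf, tolerance = 1e-12)
  }
})

test_that("zero-lag value of a train against itself is the mean square count", {
  a <- generate_poisson_train(8, 10, seed = 1)
  r <- averaged_ccg(a, a, 10, ccg_params(max_lag_ms = 10))
  m <- vapply(0:4, function(s)
    sum(bin_counts(a, 2 * s, 2 * (s + 1), 1 / 1024)^2), 0)
  expect_equal(r$values[r$delays == 0], mean(m) / 2)
  expect_gte(r$values[r$delays == 0], mean_firing_rate(a, 10))
})

test_that("independent Poisson trains give a flat CCG at the product rate", {
  a <- generate_poisson_train(20, 300, seed = 31)
  b <- generate_poisson_train(20, 300, seed = 32)
  r <- averaged_ccg(a, b, 300, ccg_params())
  expected <- 20 * 20 / 1024
  expect_lt(abs(mean(r$values) - expected) / expected, 0.1)
  # and an empty train yields an all-zero CCG
  r0 <- averaged_ccg(make_train(numeric()), b, 300, ccg_params())
  expect_true(all(r0$values == 0))
})

test_that("peak statistic: flat CCG undefined, constructed peaks recovered", {
  p <- ccg_params()
  delays <- seq(-30, 30) / 1024
  flat <- peak_statistic(rep(1, 61), delays, p)
  expect_equal(flat$zero_peak, 0)
  expect_true(is.na(flat$normalized_peak))
  set.seed(9)
  vals <- stats::rnorm(61)
  win <- abs(delays) >= 1e-3 & abs(delays) <= 25e-3
  vals[delays == 0] <- mean(vals[win]) + 3 * stats::sd(vals[win])
  ps <- peak_statistic(vals, delays, p)
  expect_equal(ps$normalized_peak, 3, tolerance = 1e-9)
  vals[delays == 0] <- mean(vals[win]) - 2 * stats::sd(vals[win])
  expect_lt(peak_statistic(vals, delays, p)$normalized_peak, 0)
})

test_that("permuting both trains' segments identically preserves the CCG", {
  a <- generate_poisson_train(10, 20, seed = 41)
  b <- generate_poisson_train(12, 20, seed = 42)
  p <- ccg_params(max_lag_ms = 10)
  set.seed(7)
  perm <- sample(10)
  rearrange <- function(tr) {
    seg <- floor(tr$spike_times / 2)
    off <- tr$spike_times - 2 * seg
    make_train(sort(2 * (match(seg + 1, perm) - 1) + off))
  }
  r1 <- averaged_ccg(a, b, 20, p)
  r2 <- averaged_ccg(rearrange(a), rearrange(b), 20, p)
  expect_equal(r2$values, r1$values, tolerance = 1e-9)
})

test_that("a fully coupled pair attains the smallest possible p-value", {
  pp <- generate_synchronous_pair(
    sync_pair_params(copy_prob_a = 1, copy_prob_b = 1, jitter_sd_ms = 0),
    300, seed = 3)
  res <- permutation_test(pp$a, pp$b, 300, ccg_params(seed = 9))
  expect_equal(res$p_value, 1 / 201)
  expect_equal(res$sign, "positive")
  expect_true(res$significant)
  expect_gte(res$p_value, 1 / 201)  # p floor from the +1 correction
})

test_that("permutation p-values respect their floor and sign convention", {
  a <- generate_poisson_train(10, 300, seed = 51)
  b <- generate_poisson_train(10, 300, seed = 52)
  res <- permutation_test(a, b, 300, ccg_params(seed = 9))
  expect_gte(res$p_value, 1 / 201)
  expect_lte(res$p_value, 1)
  expect_identical(res$sign == "none", !res$significant)
  expect_error(permutation_test(a, b, 3, ccg_params()), "2 segments")
})

test_that("analyze_all_pairs yields C(n,2) records per epoch", {
  gen <- generate_population(population_config(
    layout = data.frame(patient_id = "P1", epoch_id = "e1", n_units = 5L),
    epoch_duration_s = 60, seed = 8))
  ep <- gen$session$epochs[[1]]
  pr <- analyze_all_pairs(ep, ccg_params(seed = 10))
  expect_equal(nrow(pr), 10L)
  expect_equal(anyDuplicated(pr[c("unit_a", "unit_b")]), 0L)
  one <- epoch("e1", "P1", list(make_train(1:10)))
  expect_equal(nrow(analyze_all_pairs(one, ccg_params())), 0L)
  # pair records agree with a direct permutation_test at the same seed
  direct <- permutation_test(ep$trains[[pr$unit_a[3]]],
                             ep$trains[[pr$unit_b[3]]], 60,
                             ccg_params(seed = 10),
                             seed = unitsync:::derive_seed(10, 3))
  expect_equal(pr$p_value[3], direct$p_value)
  expect_equal(pr$zero_peak[3], direct$zero_peak)
})
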