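test_that("poisson generator: empty at rate 0, deterministic, correct mean", {
  expect_length(generate_poisson_train(0, 300, seed = 1)$spike_times, 0L)
  expect_error(generate_poisson_train(-1, 300), ">= 0")
  a <- generate_poisson_train(7, 100, seed = 42)
  b <- generate_poisson_train(7, 100, seed = 42)
  expect_identical(a$spike_times, b$spike_times)
  # law of large numbers: 500 replicates of rate 10 x 300 s
  counts <- vapply(1:500, function(i)
    length(generate_poisson_train(10, 300, seed = 1000 + i)$spike_times), 0L)
  se <- sqrt(3000 / 500)
  expect_lt(abs(mean(counts) - 3000), 3 * se)
})

test_that("bursty generator degenerates to Poisson with one spike per burst", {
  counts <- vapply(1:200, function(i)
    length(generate_bursty_train(4, 6, spikes_per_burst = 1,
                                 duration_s = 100,
                                 seed = 300 + i)$spike_times), 0L)
  # combined rate 10 sp/s over 100 s
  expect_lt(abs(mean(counts) - 1000), 3 * sqrt(1000 / 200))
  expect_error(generate_bursty_train(1, 1, intra_burst_isi_ms = 12), "< 10")
})

test_that("burst calibration hits its target and orders classes correctly", {
  realized <- function(target, rate, n = 100) {
    bp <- burst_params_for_target(target, rate)
    stats::median(vapply(seq_len(n), function(i)
      burst_index(generate_bursty_train(bp$baseline_rate, bp$burst_rate,
                                        bp$spikes_per_burst,
                                        duration_s = 300,
                                        seed = 7000 + i)), 0))
  }
  b39 <- realized(0.39, 10)
  expect_lt(abs(b39 - 0.39), 0.1)
  b015 <- realized(0.015, 1, n = 50)
  b18 <- realized(0.18, 5, n = 50)
  expect_true(b015 < b18 && b18 < b39)
})

test_that("synchronous pair: degenerate cases and coincidence surplus", {
  # copy probs (1,1), jitter 0: every master spike present in both trains
  pp <- generate_synchronous_pair(
    sync_pair_params(copy_prob_a = 1, copy_prob_b = 1, jitter_sd_ms = 0,
                     independent_rate_a = 0, independent_rate_b = 0),
    100, seed = 11)
  expect_identical(pp$a$spike_times, pp$b$spike_times)
  expect_error(sync_pair_params(copy_prob_a = 1.2), "copy probabilities")
  # copy probs (0.5, 0.5), jitter 1 ms, master 10 sp/s: surplus of
  # coincidences in a +-2 ms window ~ 10 * 0.25 * P(|N(0, sqrt(2) ms)| < 2 ms)
  w <- 0.002
  surp <- vapply(1:25, function(s) {
    pp <- generate_synchronous_pair(sync_pair_params(), 300, seed = s)
    a <- pp$a$spike_times; b <- pp$b$spike_times
    cnt <- sum(vapply(a, function(t) sum(abs(b - t) < w), 0))
    (cnt - length(a) * length(b) * 2 * w / 300) / 300
  }, 0)
  expected <- 10 * 0.25 *
    (stats::pnorm(w, 0, sqrt(2) * 1e-3) - stats::pnorm(-w, 0, sqrt(2) * 1e-3))
  expect_lt(abs(mean(surp) - expected), 0.3)
})

test_that("discharge injection: identity cases and window dominance", {
  tr <- generate_poisson_train(1, 300, seed = 21)
  expect_identical(inject_discharge(tr, 50, 0, 30, epoch_duration_s = 300),
                   tr)
  expect_identical(
    inject_discharge(tr, 50, 10, 1, baseline_rate = 1,
                     epoch_duration_s = 300, seed = 1),
    tr)
  expect_error(inject_discharge(tr, 295, 10, 30, epoch_duration_s = 300),
               "outside epoch")
  # 1 -> 30 sp/s ramp over 10 s: the injected window holds the most spikes
  wins <- seq(0, 290, by = 10)
  hits <- vapply(1:40, function(s) {
    tt <- inject_discharge(generate_poisson_train(1, 300, seed = 100 + s),
                           120, 10, 30, baseline_rate = 1,
                           epoch_duration_s = 300,
                           seed = 200 + s)$spike_times
    cnt <- vapply(wins, function(w) sum(tt >= w & tt < w + 10), 0)
    wins[which.max(cnt)] == 120
  }, TRUE)
  expect_gt(mean(hits), 0.99)
})

test_that("generated population matches the configured study shape", {
  pm <- population_metrics(1)
  m <- pm$metrics
  expect_equal(nrow(m), 222L)
  expect_equal(length(pm$gen$session$epochs), 37L)
  # determinism under the master seed
  g2 <- generate_population(population_config(seed = 1))
  expect_identical(g2$session$epochs[[5]]$trains[[1]]$spike_times,
                   pm$gen$session$epochs[[5]]$trains[[1]]$spike_times)
  # ground-truth labels cover all units and pairs count is sum of C(n,2)
  expect_setequal(pm$gen$units$unit_id, m$unit_id)
  tab <- unit_count_table(pm$gen$session)
  expect_equal(nrow(pm$gen$pairs), sum(choose(tab$n_units, 2)))
})

test_that("rendered traces have the requested noise floor and spikes", {
  vt <- render_trace(list(), duration_s = 5, noise_sd = 1, seed = 31)
  expect_lt(abs(stats::sd(vt$samples) - 1), 0.02)
  expect_error(render_trace(list(), sampling_hz = 0), "sampling_hz")
  expect_error(
    render_trace(list(make_train(20)), duration_s = 10, seed = 1),
    "beyond trace duration")
})
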