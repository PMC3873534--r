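# Independent oracles and shared cached simulations for the test suite.

# Brute-force circular lagged pair counting: the O(n^2)-style oracle for
# the spectral averaged cross-correlogram.
brute_ccg <- function(a, b, dur, seg_s, bin_s, maxlag) {
  nseg <- floor(dur / seg_s)
  nb <- round(seg_s / bin_s)
  tot <- numeric(2 * maxlag + 1)
  for (s in seq_len(nseg) - 1) {
    ca <- bin_counts(a, s * seg_s, (s + 1) * seg_s, bin_s)
    cb <- bin_counts(b, s * seg_s, (s + 1) * seg_s, bin_s)
    for (li in seq(-maxlag, maxlag)) {
      idx <- ((seq_len(nb) - 1 + li) %% nb) + 1
      tot[li + maxlag + 1] <- tot[li + maxlag + 1] + sum(ca * cb[idx])
    }
  }
  tot / nseg / seg_s
}

# Direct two-sided binomial p-value by tail summation over the minimum
# likelihood region (oracle for binomial_fraction_test at small n).
brute_binom_p <- function(k, n, p0) {
  d <- stats::dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# Exhaustive scan: does any retained cross-channel pair violate the
# duplicate rule (later spike < thr after an earlier retained spike)?
dedup_violations <- function(trains, threshold_us = 100) {
  tt <- unlist(lapply(trains, `[[`, "spike_times"))
  ch <- rep(vapply(trains, `[[`, 0L, "channel_id"),
            vapply(trains, function(tr) length(tr$spike_times), 0L))
  n <- length(tt)
  bad <- 0L
  if (n < 2) return(0L)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || ch[i] == ch[j]) next
    dt <- tt[j] - tt[i]
    if (dt >= 0 && dt < threshold_us * 1e-6 &&
        !(dt == 0 && ch[j] < ch[i])) bad <- bad + 1L
  }
  bad
}

# Shared cache: permutation-test p-values for independent Poisson pairs at
# a given rate (used by the type-I, uniformity and rate-invariance checks).
.null_cache <- new.env(parent = emptyenv())
null_pair_pvalues <- function(rate, n_pairs, seed_base) {
  key <- paste(rate, n_pairs, seed_base, sep = "_")
  if (!is.null(.null_cache[[key]])) return(.null_cache[[key]])
  ps <- vapply(seq_len(n_pairs), function(i) {
    a <- generate_poisson_train(rate, 300, seed = seed_base + 2 * i)
    b <- generate_poisson_train(rate, 300, seed = seed_base + 2 * i + 1)
    permutation_test(a, b, 300, ccg_params(seed = seed_base + 90000 + i))$p_value
  }, 0)
  .null_cache[[key]] <- ps
  ps
}

# Shared cache: full generated populations with unit metrics, reused by
# the mixture / correlation recovery checks across several seeds.
.pop_cache <- new.env(parent = emptyenv())
population_metrics <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.pop_cache[[key]])) return(.pop_cache[[key]])
  gen <- generate_population(population_config(seed = seed))
  m <- unit_metrics(dedup_session(gen$session), detect_discharges = FALSE)
  out <- list(gen = gen, metrics = m)
  .pop_cache[[key]] <- out
  out
}

make_train <- function(times, channel = 1L, unit = "u1", epoch = "e1") {
  spike_train(unit, channel, times, epoch)
}
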