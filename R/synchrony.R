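#' Cross-correlogram parameters
#'
#' Defaults reproduce the reference analysis: each epoch is divided into
#' 2-s segments; spike counts are binned at 1/1024 s; per-segment circular
#' cross-correlations (computed spectrally) are averaged; the zero-delay
#' peak is referenced to the mean and SD of CCG values in the 1-25 ms
#' delay window (both signs pooled); significance comes from 200 random
#' shuffles of the second train's segment order.
#'
#' @param segment_s Segment length in seconds; a trailing partial segment
#'   is dropped.
#' @param bin_s Bin width in seconds.
#' @param n_permutations Number of segment shuffles (>= 1).
#' @param norm_window_ms Two-element delay range (ms) for the baseline
#'   mean/SD window.
#' @param alpha Significance level.
#' @param max_lag_ms Largest delay (ms) retained in reported CCG curves.
#' @param statistic Permutation statistic: `"raw"` (baseline-subtracted
#'   zero-lag value; shuffling preserves the baseline) or `"normalized"`
#'   (the same divided by the window SD).
#' @param seed Seed for the permutation draws.
#' @return An object of class `ccg_params`.
#' @export
ccg_params <- function(segment_s = 2, bin_s = 1 / 1024,
                       n_permutations = 200, norm_window_ms = c(1, 25),
                       alpha = 0.05, max_lag_ms = 30,
                       statistic = c("raw", "normalized"), seed = 1L) {
  statistic <- match.arg(statistic)
  if (bin_s <= 0 || segment_s <= 0) stopf("segment_s and bin_s must be > 0")
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  if (length(norm_window_ms) != 2 || diff(norm_window_ms) <= 0)
    stopf("norm_window_ms must be an increasing pair")
  structure(list(segment_s = segment_s, bin_s = bin_s,
                 n_permutations = as.integer(n_permutations),
                 norm_window_ms = norm_window_ms, alpha = alpha,
                 max_lag_ms = max_lag_ms, statistic = statistic,
                 seed = seed), class = "ccg_params")
}

#' Bin spike counts on a regular grid
#'
#' Counts spikes in half-open bins `[k*bin_s, (k+1)*bin_s)` between
#' `t_start` and `t_end`; a spike exactly on a boundary belongs to the
#' later bin. The sum of counts equals the number of spikes in
#' `[t_start, t_end)`.
#'
#' @param train A [spike_train()] or numeric vector of spike times.
#' @param t_start,t_end Segment bounds in seconds.
#' @param bin_s Bin width in seconds.
#' @return Integer vector of per-bin counts.
#' @export
bin_counts <- function(train, t_start, t_end, bin_s) {
  tt <- if (inherits(train, "spike_train")) train$spike_times else train
  nb <- round((t_end - t_start) / bin_s)
  tt <- tt[tt >= t_start & tt < t_end]
  idx <- floor((tt - t_start) / bin_s)
  idx[idx >= nb] <- nb - 1  # guard against float edge at t_end
  tabulate(idx + 1L, nbins = nb)
}

# nbins x nseg matrix of per-segment binned counts; trailing partial
# segment dropped.
segment_count_matrix <- function(train, duration_s, segment_s, bin_s) {
  nseg <- floor(duration_s / segment_s)
  if (nseg < 1) stopf("epoch shorter than one segment")
  nb <- round(segment_s / bin_s)
  tt <- if (inherits(train, "spike_train")) train$spike_times else train
  tt <- tt[tt < nseg * segment_s]
  idx <- floor(tt / bin_s)
  seg <- idx %/% nb
  within <- idx - seg * nb
  m <- matrix(0L, nb, nseg)
  if (length(tt)) {
    flat <- within + seg * nb + 1
    cnt <- tabulate(flat, nbins = nb * nseg)
    m[] <- cnt
  }
  m
}

# circular cross-correlation counts for one pair of frequency-domain
# segment matrices, summed over paired segments (a_s with b_{perm(s)})
ccg_counts_from_fft <- function(Fa, Fb, pairing = seq_len(ncol(Fa))) {
  G <- rowSums(Conj(Fa) * Fb[, pairing, drop = FALSE])
  Re(stats::fft(G, inverse = TRUE)) / nrow(Fa)
}

lag_indices <- function(nb, lags) ifelse(lags >= 0, lags + 1L, nb + lags + 1L)

#' Averaged cross-correlogram of two spike trains
#'
#' Bins both trains at `bin_s` within each `segment_s` segment, computes
#' the circular cross-correlation of the two count sequences of every
#' segment through the frequency domain, converts counts per lag to a
#' coincidence rate (counts / segment length), and averages over segments.
#' Positive delays mean the second train fires after the first.
#'
#' @param train_a,train_b [spike_train()]s from the same epoch.
#' @param duration_s Epoch duration in seconds.
#' @param params A [ccg_params()].
#' @return An object of class `ccg_result`: `delays` (s), `values`
#'   (coincidences/s), `zero_peak`, `normalized_peak`, `p_value` (`NA`
#'   until [permutation_test()]), `sign`, `significant`, `n_segments`.
#' @export
averaged_ccg <- function(train_a, train_b, duration_s,
                         params = ccg_params()) {
  A <- segment_count_matrix(train_a, duration_s, params$segment_s, params$bin_s)
  B <- segment_count_matrix(train_b, duration_s, params$segment_s, params$bin_s)
  nb <- nrow(A); S <- ncol(A)
  Fa <- stats::mvfft(A + 0); Fb <- stats::mvfft(B + 0)
  counts <- ccg_counts_from_fft(Fa, Fb)
  maxl <- min(nb %/% 2 - 1L, round(params$max_lag_ms / 1000 / params$bin_s))
  lags <- -maxl:maxl
  values <- counts[lag_indices(nb, lags)] / S / params$segment_s
  pk <- peak_statistic(values, lags * params$bin_s, params)
  structure(list(delays = lags * params$bin_s, values = values,
                 zero_peak = pk$zero_peak,
                 normalized_peak = pk$normalized_peak,
                 p_value = NA_real_, sign = NA_character_,
                 significant = NA, n_segments = S),
            class = "ccg_result")
}

#' Zero-delay peak statistic of a CCG
#'
#' `zero_peak` is the CCG value at the zero-lag bin minus the mean of the
#' values whose delay magnitude falls in the normalization window (1-25 ms
#' by default, both delay signs pooled); `normalized_peak` divides by the
#' SD over the same window. A flat CCG (zero window SD) yields an
#' undefined (`NA`) normalized peak.
#'
#' @param values CCG values (coincidences/s).
#' @param delays Delays in seconds, same length as `values`, containing 0.
#' @param params A [ccg_params()].
#' @return List with `zero_peak` and `normalized_peak`.
#' @export
peak_statistic <- function(values, delays, params = ccg_params()) {
  iz <- which(delays == 0)
  if (length(iz) != 1) stopf("delays must contain a single zero lag")
  w <- params$norm_window_ms / 1000
  win <- abs(delays) >= w[1] & abs(delays) <= w[2]
  if (!any(win)) stopf("CCG does not cover the normalization window")
  base <- values[win]
  zero_peak <- values[iz] - mean(base)
  s <- stats::sd(base)
  list(zero_peak = zero_peak,
       normalized_peak = if (is.finite(s) && s > 0) zero_peak / s else NA_real_)
}

# weight vector over circular lag bins implementing the raw zero-peak
# statistic as a linear functional of the CCG counts
peak_weight_fft <- function(nb, bin_s, norm_window_ms) {
  w <- numeric(nb)
  lmax <- nb %/% 2 - 1L
  lags <- -lmax:lmax
  wsec <- norm_window_ms / 1000
  win <- abs(lags) * bin_s >= wsec[1] & abs(lags) * bin_s <= wsec[2]
  idx <- lag_indices(nb, lags)
  w[idx[win]] <- -1 / sum(win)
  w[1] <- 1  # zero lag
  stats::fft(w)
}

#' Segment-shuffle permutation test of the zero-delay CCG peak
#'
#' Recomputes the averaged CCG peak statistic after randomly permuting the
#' order of the second train's 2-s segments, `n_permutations` times
#' (permutations without replacement of segment order; the identity
#' permutation may occur among the draws). Shuffling preserves both
#' trains' firing rates while destroying fine-time synchrony, so the
#' resulting two-sided empirical p-value,
#' `(1 + #(|perm| >= |observed|)) / (n_permutations + 1)`,
#' is independent of firing rate.
#'
#' @inheritParams averaged_ccg
#' @param seed Overrides `params$seed` for the permutation draws.
#' @return A complete `ccg_result` (see [averaged_ccg()]) with `p_value`,
#'   `sign` ("positive"/"negative"/"none") and `significant` filled in,
#'   plus `perm_stats` (the permutation distribution) and
#'   `observed_stat`.
#' @export
permutation_test <- function(train_a, train_b, duration_s,
                             params = ccg_params(), seed = NULL) {
  A <- segment_count_matrix(train_a, duration_s, params$segment_s, params$bin_s)
  B <- segment_count_matrix(train_b, duration_s, params$segment_s, params$bin_s)
  S <- ncol(A)
  if (S < 2) stopf("need at least 2 segments for the permutation test")
  res <- averaged_ccg(train_a, train_b, duration_s, params)
  seed <- seed %||% params$seed
  nb <- nrow(A)
  Fa <- stats::mvfft(A + 0); Fb <- stats::mvfft(B + 0)
  perms <- with_seed(seed, replicate(params$n_permutations, sample.int(S),
                                     simplify = FALSE))
  scale <- 1 / (S * params$segment_s)
  if (params$statistic == "raw") {
    # phi[s, t] = raw peak contribution of pairing segment s of A with
    # segment t of B; every permutation statistic is then a mean of S
    # entries of this matrix.
    What <- peak_weight_fft(nb, params$bin_s, params$norm_window_ms)
    M <- Conj(Fa * What)
    phi <- Re(t(M) %*% Fb) / nb
    obs <- mean(diag(phi)) / params$segment_s
    perm_stats <- vapply(perms, function(p)
      mean(phi[cbind(seq_len(S), p)]) / params$segment_s, 0)
  } else {
    stat_of <- function(pairing) {
      counts <- ccg_counts_from_fft(Fa, Fb, pairing)
      maxl <- min(nb %/% 2 - 1L, round(params$max_lag_ms / 1000 / params$bin_s))
      lags <- -maxl:maxl
      vals <- counts[lag_indices(nb, lags)] * scale
      peak_statistic(vals, lags * params$bin_s, params)$normalized_peak
    }
    obs <- stat_of(seq_len(S))
    perm_stats <- vapply(perms, stat_of, 0)
  }
  if (!is.finite(obs)) {
    res$p_value <- NA_real_; res$sign <- NA_character_
    res$significant <- NA
    res$observed_stat <- obs; res$perm_stats <- perm_stats
    return(res)
  }
  p <- (1 + sum(abs(perm_stats) >= abs(obs), na.rm = TRUE)) /
    (params$n_permutations + 1)
  res$p_value <- p
  res$significant <- p <= params$alpha
  res$sign <- if (!res$significant) "none" else
    if (res$zero_peak > 0) "positive" else "negative"
  res$observed_stat <- obs
  res$perm_stats <- perm_stats
  res
}

#' Analyze all unit pairs within an epoch
#'
#' Runs [permutation_test()] on every unordered pair of units in the epoch
#' (`n * (n - 1) / 2` records for `n` units). Per-unit segment FFTs are
#' computed once and shared across pairs. Pairs recorded on the same
#' channel are retained; the duplicate-spike rule is assumed to have been
#' applied already.
#'
#' @param ep An [epoch()].
#' @param params A [ccg_params()].
#' @param seed Base seed; each pair uses a derived stream.
#' @return `data.frame` with one row per pair: `patient_id`, `epoch_id`,
#'   `unit_a`, `unit_b`, `zero_peak`, `normalized_peak`, `p_value`,
#'   `sign`, `significant`.
#' @export
analyze_all_pairs <- function(ep, params = ccg_params(), seed = NULL) {
  stopifnot(inherits(ep, "epoch"))
  empty <- data.frame(patient_id = character(), epoch_id = character(),
                      unit_a = character(), unit_b = character(),
                      zero_peak = numeric(), normalized_peak = numeric(),
                      p_value = numeric(), sign = character(),
                      significant = logical(), stringsAsFactors = FALSE)
  n <- length(ep$trains)
  if (n < 2) return(empty)
  seed <- seed %||% params$seed
  trains <- unname(ep$trains)
  ids <- vapply(trains, `[[`, "", "unit_id")
  ffts <- lapply(trains, function(tr)
    stats::mvfft(segment_count_matrix(tr, ep$duration_s, params$segment_s,
                                      params$bin_s) + 0))
  nb <- nrow(ffts[[1]]); S <- ncol(ffts[[1]])
  What <- peak_weight_fft(nb, params$bin_s, params$norm_window_ms)
  maxl <- min(nb %/% 2 - 1L, round(params$max_lag_ms / 1000 / params$bin_s))
  lags <- -maxl:maxl
  lidx <- lag_indices(nb, lags)
  cmb <- utils::combn(n, 2)
  rows <- vector("list", ncol(cmb))
  for (k in seq_len(ncol(cmb))) {
    i <- cmb[1, k]; j <- cmb[2, k]
    if (params$statistic == "normalized") {
      r <- permutation_test(trains[[i]], trains[[j]], ep$duration_s, params,
                            seed = derive_seed(seed, k))
      rows[[k]] <- data.frame(
        patient_id = ep$patient_id, epoch_id = ep$epoch_id,
        unit_a = ids[i], unit_b = ids[j],
        zero_peak = r$zero_peak, normalized_peak = r$normalized_peak,
        p_value = r$p_value, sign = r$sign %||% NA_character_,
        significant = r$significant, stringsAsFactors = FALSE)
      next
    }
    Fa <- ffts[[i]]; Fb <- ffts[[j]]
    counts <- ccg_counts_from_fft(Fa, Fb)
    vals <- counts[lidx] / (S * params$segment_s)
    pk <- peak_statistic(vals, lags * params$bin_s, params)
    perms <- with_seed(derive_seed(seed, k),
                       replicate(params$n_permutations, sample.int(S),
                                 simplify = FALSE))
    M <- Conj(Fa * What)
    phi <- Re(t(M) %*% Fb) / nb
    obs <- mean(diag(phi)) / params$segment_s
    perm_stats <- vapply(perms, function(p)
      mean(phi[cbind(seq_len(S), p)]) / params$segment_s, 0)
    p <- (1 + sum(abs(perm_stats) >= abs(obs))) / (params$n_permutations + 1)
    sig <- p <= params$alpha
    rows[[k]] <- data.frame(
      patient_id = ep$patient_id, epoch_id = ep$epoch_id,
      unit_a = ids[i], unit_b = ids[j],
      zero_peak = pk$zero_peak, normalized_peak = pk$normalized_peak,
      p_value = p,
      sign = if (!sig) "none" else if (pk$zero_peak > 0) "positive" else "negative",
      significant = sig, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
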