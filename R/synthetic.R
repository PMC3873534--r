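#' Default epoch layout of the emulated study
#'
#' Returns the per-epoch unit counts used as the default shape of generated
#' sessions: 14 patients, 37 five-minute epochs, 222 units in total (mean 6
#' units per epoch), mirroring the intra-operative recording series the
#' simulator emulates.
#'
#' @return `data.frame` with `patient_id`, `epoch_id`, `n_units`.
#' @export
default_epoch_layout <- function() {
  utils::read.csv(system.file("extdata", "epoch_unit_counts.csv",
                              package = "unitsync"),
                  stringsAsFactors = FALSE)
}

#' Population generator configuration
#'
#' Holds the statistical targets of the synthetic population: two
#' firing-rate classes (log-normal around medians 0.6 and 15.0 sp/s, class
#' boundary 2 sp/s), three burst-index classes (medians 0.015, 0.18, 0.39),
#' a positive rate-burst correlation (target Pearson rho 0.66), a
#' controllable fraction of synchronously coupled unit pairs concentrated
#' among fast units, and rare evolving discharges (3.6% of units).
#'
#' @param layout Epoch layout `data.frame` (`patient_id`, `epoch_id`,
#'   `n_units`); defaults to [default_epoch_layout()].
#' @param epoch_duration_s Epoch duration in seconds.
#' @param rate_class_mix Proportions of (slow, fast) units; must sum to 1.
#' @param slow_rate_median,fast_rate_median Class median rates, sp/s.
#' @param rate_class_sd Raw-scale SDs of the two rate classes (sp/s); each
#'   class is a low-truncated Gaussian centered on its median, so the rate
#'   histogram is a two-Gaussian mixture as the downstream model assumes.
#' @param burst_class_medians Target burst-index medians of the three
#'   burst classes.
#' @param burst_class_mix Proportions of the three burst classes.
#' @param burst_sdlog Within-class log-scale spread of per-unit burst
#'   targets, so each class forms a smooth unimodal cloud around its
#'   median rather than a point mass.
#' @param target_rate_burst_rho Target Pearson correlation between mean
#'   rate and burst index (achieved through a shared latent Gaussian whose
#'   correlation `latent_rho` was calibrated once by pilot simulation).
#' @param latent_rho Correlation of the latent (rate, burst) Gaussian.
#' @param sync_pair_fraction Target fraction of unit pairs that are truly
#'   coupled (members of a shared-drive assembly), per epoch.
#' @param sync_fast_bias Relative weight of fast units when sampling
#'   assembly members (> 1 concentrates coupling among fast units).
#' @param sync_coupling Fraction of a coupled unit's spikes drawn from the
#'   assembly master train.
#' @param sync_master_rate Assembly master train rate, sp/s.
#' @param sync_jitter_ms SD of the jitter applied to copied master spikes.
#' @param discharge_unit_fraction Fraction of units receiving one injected
#'   evolving discharge.
#' @param discharge_peak_rate,discharge_duration_s Discharge shape.
#' @param seed Master seed; all unit/pair streams are derived from it.
#' @return An object of class `population_config`.
#' @export
population_config <- function(layout = default_epoch_layout(),
                              epoch_duration_s = 300,
                              rate_class_mix = c(slow = 0.45, fast = 0.55),
                              slow_rate_median = 0.6,
                              fast_rate_median = 15.0,
                              rate_class_sd = c(slow = 0.35, fast = 5),
                              burst_class_medians = c(0.015, 0.18, 0.39),
                              burst_class_mix = c(0.40, 0.35, 0.25),
                              burst_sdlog = 0.25,
                              target_rate_burst_rho = 0.66,
                              latent_rho = 0.8,
                              sync_pair_fraction = 0.51,
                              sync_fast_bias = 4,
                              sync_coupling = 0.3,
                              sync_master_rate = 10,
                              sync_jitter_ms = 2,
                              discharge_unit_fraction = 0.036,
                              discharge_peak_rate = 30,
                              discharge_duration_s = 10,
                              seed = 1L) {
  stopifnot(all(c("patient_id", "epoch_id", "n_units") %in% names(layout)))
  if (epoch_duration_s <= 0) stopf("epoch_duration_s must be > 0")
  if (abs(sum(rate_class_mix) - 1) > 1e-8) stopf("rate_class_mix must sum to 1")
  if (abs(sum(burst_class_mix) - 1) > 1e-8) stopf("burst_class_mix must sum to 1")
  if (any(burst_class_medians <= 0) || slow_rate_median <= 0 ||
      fast_rate_median <= 0)
    stopf("class medians must be > 0")
  bad01 <- function(p) any(p < 0 | p > 1)
  if (bad01(c(sync_pair_fraction, discharge_unit_fraction, sync_coupling)))
    stopf("proportions must lie in [0, 1]")
  structure(as.list(environment()), class = "population_config")
}

#' Generate a homogeneous Poisson spike train
#'
#' Null model used for the permutation test's type-I properties: spike
#' count is Poisson with mean `rate * duration_s`, times uniform.
#'
#' @param rate Rate in sp/s (>= 0).
#' @param duration_s Duration in seconds.
#' @param seed Optional seed (reproducible for a fixed value).
#' @param unit_id,channel_id,epoch_id Train identity fields.
#' @return A [spike_train()].
#' @export
generate_poisson_train <- function(rate, duration_s, seed = NULL,
                                   unit_id = "u1", channel_id = 1L,
                                   epoch_id = "e1") {
  if (rate < 0) stopf("rate must be >= 0")
  if (duration_s <= 0) stopf("duration_s must be > 0")
  times <- with_seed(seed, {
    n <- stats::rpois(1, rate * duration_s)
    sort(stats::runif(n, 0, duration_s))
  })
  spike_train(unit_id, channel_id, times, epoch_id)
}

#' Burst-generator parameters targeting a given burst index
#'
#' Inverts the approximate relation between the two-state renewal
#' parameters and the realized burst index B (ratio of interspike
#' intervals < 10 ms to those >= 10 ms). Two sources of short ISIs are
#' modeled: intra-burst intervals (`lambda_b * (nbar - 1)` per second,
#' essentially all short) and chance coincidences between events — burst
#' onsets plus baseline spikes arrive at rate
#' `lambda_e = lambda_0 + lambda_b`, so a fraction
#' `p = 1 - exp(-lambda_e * thr)` of the inter-event gaps falls below the
#' threshold. Thus
#' `B ~= (lambda_b (nbar-1) + lambda_e p) / (lambda_e (1 - p))`,
#' which is solved for `lambda_b` at fixed `nbar` subject to the total
#' rate `r = lambda_0 + nbar * lambda_b`. Chance coincidences put a floor
#' on B at a given rate — a fast Poisson unit is never ISI-quiet — so an
#' unattainably low target returns a pure Poisson train.
#'
#' @param target_b Target burst index (>= 0).
#' @param total_rate Total mean rate in sp/s.
#' @param spikes_per_burst Mean spikes per burst event (> 1 unless
#'   `target_b` is 0).
#' @param isi_threshold_ms Short-ISI threshold, ms.
#' @return List with `baseline_rate`, `burst_rate`, `spikes_per_burst`.
#' @export
burst_params_for_target <- function(target_b, total_rate,
                                    spikes_per_burst = 3,
                                    isi_threshold_ms = 10) {
  stopifnot(target_b >= 0, total_rate >= 0)
  thr <- isi_threshold_ms / 1000
  nbar <- spikes_per_burst
  b_of <- function(lb) {
    le <- total_rate - (nbar - 1) * lb  # event rate lambda_0 + lambda_b
    p <- 1 - exp(-le * thr)
    (lb * (nbar - 1) + le * p) / (le * (1 - p))
  }
  if (total_rate == 0)
    return(list(baseline_rate = 0, burst_rate = 0, spikes_per_burst = 1))
  if (target_b <= b_of(0))  # at or below the chance floor: pure Poisson
    return(list(baseline_rate = total_rate, burst_rate = 0,
                spikes_per_burst = 1))
  lb_max <- total_rate / nbar
  lb <- if (b_of(lb_max) <= target_b) lb_max else
    stats::uniroot(function(l) b_of(l) - target_b, c(0, lb_max),
                   tol = 1e-10)$root
  list(baseline_rate = max(0, total_rate - nbar * lb), burst_rate = lb,
       spikes_per_burst = nbar)
}

#' Generate a bursty spike train (two-state renewal process)
#'
#' Burst events arrive as a Poisson process at `burst_rate`; each burst
#' carries `1 + Poisson(spikes_per_burst - 1)` spikes whose intra-burst
#' ISIs are gamma distributed (shape 2) with mean `intra_burst_isi_ms`.
#' An independent Poisson baseline at `baseline_rate` is superimposed.
#' With `spikes_per_burst = 1` the process degenerates to homogeneous
#' Poisson at the combined rate.
#'
#' @param baseline_rate,burst_rate Rates in sp/s (>= 0).
#' @param spikes_per_burst Mean number of spikes per burst (>= 1).
#' @param intra_burst_isi_ms Mean intra-burst ISI in ms (must be < 10).
#' @param duration_s Duration in seconds.
#' @param seed Optional seed.
#' @param unit_id,channel_id,epoch_id Train identity fields.
#' @return A [spike_train()].
#' @export
generate_bursty_train <- function(baseline_rate, burst_rate,
                                  spikes_per_burst = 3,
                                  intra_burst_isi_ms = 4,
                                  duration_s = 300, seed = NULL,
                                  unit_id = "u1", channel_id = 1L,
                                  epoch_id = "e1") {
  if (baseline_rate < 0 || burst_rate < 0) stopf("rates must be >= 0")
  if (spikes_per_burst < 1) stopf("spikes_per_burst must be >= 1")
  if (intra_burst_isi_ms >= 10)
    stopf("intra_burst_isi_ms must be < 10 (short-ISI regime)")
  times <- with_seed(seed, {
    base <- stats::runif(stats::rpois(1, baseline_rate * duration_s),
                         0, duration_s)
    nb <- stats::rpois(1, burst_rate * duration_s)
    burst_onsets <- stats::runif(nb, 0, duration_s)
    burst_spikes <- unlist(lapply(burst_onsets, function(t0) {
      nsp <- 1L + stats::rpois(1, spikes_per_burst - 1)
      if (nsp == 1L) return(t0)
      isis <- stats::rgamma(nsp - 1L, shape = 2,
                            scale = intra_burst_isi_ms / 2000)
      t0 + c(0, cumsum(isis))
    }))
    tt <- sort(c(base, burst_spikes))
    tt[tt <= duration_s]
  })
  spike_train(unit_id, channel_id, times, epoch_id)
}

#' Parameters of a synchronously firing pair
#'
#' Mechanism used to realize pairs that fire together in excess of chance:
#' both trains receive thinned, jittered copies of a shared master Poisson
#' train plus independent Poisson background. The zero-lag coincidence
#' surplus is `master_rate * copy_prob_a * copy_prob_b` per second
#' (spread over lags by the jitter).
#'
#' @param master_rate Shared master train rate, sp/s.
#' @param copy_prob_a,copy_prob_b Copy (thinning) probabilities in [0, 1].
#' @param jitter_sd_ms SD of Gaussian jitter applied to each copy, ms.
#' @param independent_rate_a,independent_rate_b Background rates, sp/s.
#' @return An object of class `sync_pair_params`.
#' @export
sync_pair_params <- function(master_rate = 10, copy_prob_a = 0.5,
                             copy_prob_b = 0.5, jitter_sd_ms = 1,
                             independent_rate_a = 5, independent_rate_b = 5) {
  if (copy_prob_a < 0 || copy_prob_a > 1 || copy_prob_b < 0 || copy_prob_b > 1)
    stopf("copy probabilities must lie in [0, 1]")
  if (master_rate < 0 || independent_rate_a < 0 || independent_rate_b < 0)
    stopf("rates must be >= 0")
  structure(as.list(environment()), class = "sync_pair_params")
}

#' Generate a synchronously firing pair of spike trains
#'
#' @param params A [sync_pair_params()].
#' @param duration_s Duration in seconds.
#' @param seed Optional seed.
#' @param epoch_id Epoch identifier for both trains.
#' @return List of two [spike_train()]s (`a`, `b`).
#' @export
generate_synchronous_pair <- function(params = sync_pair_params(),
                                      duration_s = 300, seed = NULL,
                                      epoch_id = "e1") {
  stopifnot(inherits(params, "sync_pair_params"))
  with_seed(seed, {
    master <- stats::runif(stats::rpois(1, params$master_rate * duration_s),
                           0, duration_s)
    copy <- function(p, jitter_ms) {
      keep <- master[stats::runif(length(master)) < p]
      if (jitter_ms > 0 && length(keep))
        keep <- keep + stats::rnorm(length(keep), 0, jitter_ms / 1000)
      keep[keep >= 0 & keep <= duration_s]
    }
    a <- c(copy(params$copy_prob_a, params$jitter_sd_ms),
           stats::runif(stats::rpois(1, params$independent_rate_a * duration_s),
                        0, duration_s))
    b <- c(copy(params$copy_prob_b, params$jitter_sd_ms),
           stats::runif(stats::rpois(1, params$independent_rate_b * duration_s),
                        0, duration_s))
    list(a = spike_train("a", 1L, sort(a), epoch_id),
         b = spike_train("b", 2L, sort(b), epoch_id))
  })
}

#' Inject an evolving discharge into a spike train
#'
#' Superimposes an inhomogeneous Poisson process whose rate ramps linearly
#' from 0 up to `peak_rate - baseline_rate` at the window midpoint and back
#' to 0 (triangular envelope), emulating a transient self-limited
#' escalation of firing above baseline.
#'
#' @param train A [spike_train()].
#' @param onset_s,duration_s Discharge window (must lie within the epoch).
#' @param peak_rate Peak rate at the window midpoint, sp/s.
#' @param baseline_rate The train's baseline rate (subtracted from
#'   `peak_rate` to get the added intensity).
#' @param epoch_duration_s Epoch duration for range checking.
#' @param seed Optional seed.
#' @return The train with the discharge spikes merged in.
#' @export
inject_discharge <- function(train, onset_s, duration_s, peak_rate,
                             baseline_rate = 0, epoch_duration_s = Inf,
                             seed = NULL) {
  stopifnot(inherits(train, "spike_train"))
  if (duration_s < 0) stopf("duration_s must be >= 0")
  if (onset_s < 0 || onset_s + duration_s > epoch_duration_s)
    stopf("discharge window outside epoch")
  extra_peak <- max(0, peak_rate - baseline_rate)
  if (duration_s == 0 || extra_peak == 0) return(train)
  times <- with_seed(seed, {
    n <- stats::rpois(1, extra_peak * duration_s / 2)  # triangle area
    # symmetric triangular distribution over the window
    u <- stats::runif(n)
    x <- ifelse(u < 0.5, sqrt(u / 2), 1 - sqrt((1 - u) / 2))
    onset_s + x * duration_s
  })
  spike_train(train$unit_id, train$channel_id,
              sort(c(train$spike_times, times)), train$epoch_id)
}

#' Generate a synthetic population session with ground truth
#'
#' Builds a full multi-patient session whose unit-level statistics approach
#' the configured targets: log-normal rate classes, burst classes realized
#' through the two-state renewal generator, rate-burst correlation induced
#' by a shared latent Gaussian, per-epoch synchronous assemblies whose
#' members share a jittered master train (membership biased toward fast
#' units), per-epoch anesthesia covariates, and rare injected discharges.
#'
#' @param config A [population_config()].
#' @return List with elements `session` ([spike_session()]), `units`
#'   (ground-truth `data.frame`: ids, true classes, target rate/burst,
#'   assembly membership, discharge window) and `pairs` (ground-truth
#'   coupling flag per within-epoch unordered pair).
#' @export
generate_population <- function(config = population_config()) {
  stopifnot(inherits(config, "population_config"))
  lay <- config$layout
  dur <- config$epoch_duration_s
  master_seed <- config$seed
  p_slow <- config$rate_class_mix[[1]]
  bcut <- cumsum(config$burst_class_mix)[1:2]

  unit_rows <- list(); pair_rows <- list(); epochs <- list()
  uidx <- 0L
  for (i in seq_len(nrow(lay))) {
    n <- lay$n_units[i]
    pid <- lay$patient_id[i]
    eid <- paste(pid, lay$epoch_id[i], sep = "_")
    ep_seed <- derive_seed(master_seed, 100000 + i)

    # latent bivariate Gaussian coupling rate class/level and burst level
    lat <- with_seed(ep_seed, {
      z1 <- stats::rnorm(n)
      z2 <- config$latent_rho * z1 +
        sqrt(1 - config$latent_rho^2) * stats::rnorm(n)
      cbind(z1, z2)
    })
    rate_class <- ifelse(stats::pnorm(lat[, 1]) < p_slow, "slow", "fast")
    # class membership comes from the latent Gaussian; within-class spread
    # is an independent truncated-normal deviate so each class is a single
    # Gaussian-shaped mode on the raw rate axis
    u <- with_seed(derive_seed(ep_seed, 6), stats::runif(n))
    rtrunc <- function(mu, sd, lo) {
      plo <- stats::pnorm((lo - mu) / sd)
      mu + sd * stats::qnorm(plo + u * (1 - plo))
    }
    rates <- ifelse(rate_class == "slow",
                    rtrunc(config$slow_rate_median,
                           config$rate_class_sd[["slow"]], 0.02),
                    rtrunc(config$fast_rate_median,
                           config$rate_class_sd[["fast"]], 2))
    u2 <- stats::pnorm(lat[, 2])
    burst_class <- cut(u2, c(-Inf, bcut, Inf), labels = c("low", "mid", "high"))
    bjit <- with_seed(derive_seed(ep_seed, 7), stats::rnorm(n))
    target_b <- config$burst_class_medians[as.integer(burst_class)] *
      exp(config$burst_sdlog * bjit)

    # synchronous assembly: size chosen so C(a,2)/C(n,2) ~ sync_pair_fraction
    a_size <- if (n >= 2 && config$sync_pair_fraction > 0)
      max(2L, round(sqrt(config$sync_pair_fraction) * n)) else 0L
    w <- ifelse(rate_class == "fast", config$sync_fast_bias, 1)
    members <- if (a_size > 0)
      with_seed(derive_seed(ep_seed, 1),
                sample.int(n, a_size, prob = w)) else integer()
    master <- if (a_size > 0)
      with_seed(derive_seed(ep_seed, 2), {
        nm <- stats::rpois(1, config$sync_master_rate * dur)
        sort(stats::runif(nm, 0, dur))
      }) else numeric()

    # rare evolving discharges
    has_dis <- with_seed(derive_seed(ep_seed, 3),
                         stats::runif(n) < config$discharge_unit_fraction)
    dis_onset <- with_seed(derive_seed(ep_seed, 4),
                           stats::runif(n, 0.1 * dur,
                                        0.9 * dur - config$discharge_duration_s))

    trains <- vector("list", n)
    for (j in seq_len(n)) {
      uidx <- uidx + 1L
      useed <- derive_seed(master_seed, uidx)
      uid <- sprintf("u%03d", uidx)
      in_asm <- j %in% members
      # calibrate bursts against the unit's *total* rate (independent part
      # plus master copies), then carve the master contribution out of the
      # baseline so coupled units still realize their burst-index target
      bp <- burst_params_for_target(target_b[j], rates[j])
      if (in_asm)
        bp$baseline_rate <- max(0, bp$baseline_rate -
                                  config$sync_coupling * rates[j])
      tr <- generate_bursty_train(bp$baseline_rate, bp$burst_rate,
                                  bp$spikes_per_burst,
                                  duration_s = dur, seed = useed,
                                  unit_id = uid,
                                  channel_id = 1L + (j - 1L) %% 8L,
                                  epoch_id = eid)
      if (in_asm && length(master)) {
        pcopy <- min(1, config$sync_coupling * rates[j] / config$sync_master_rate)
        copies <- with_seed(derive_seed(useed, 7), {
          keep <- master[stats::runif(length(master)) < pcopy]
          keep <- keep + stats::rnorm(length(keep), 0,
                                      config$sync_jitter_ms / 1000)
          keep[keep >= 0 & keep <= dur]
        })
        tr <- spike_train(uid, tr$channel_id,
                          sort(c(tr$spike_times, copies)), eid)
      }
      if (has_dis[j])
        tr <- inject_discharge(tr, dis_onset[j], config$discharge_duration_s,
                               config$discharge_peak_rate,
                               baseline_rate = rates[j],
                               epoch_duration_s = dur,
                               seed = derive_seed(useed, 8))
      trains[[j]] <- tr
      unit_rows[[uidx]] <- data.frame(
        unit_id = uid, patient_id = pid, epoch_id = eid,
        true_rate_class = rate_class[j], true_burst_class = as.character(burst_class[j]),
        target_rate = rates[j], target_burst_index = target_b[j],
        in_assembly = in_asm, has_discharge = has_dis[j],
        discharge_onset_s = ifelse(has_dis[j], dis_onset[j], NA_real_),
        discharge_duration_s = ifelse(has_dis[j], config$discharge_duration_s,
                                      NA_real_),
        stringsAsFactors = FALSE)
    }
    if (n >= 2) {
      cmb <- utils::combn(n, 2)
      ids <- vapply(trains, `[[`, "", "unit_id")
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        patient_id = pid, epoch_id = eid,
        unit_a = ids[cmb[1, ]], unit_b = ids[cmb[2, ]],
        true_coupled = cmb[1, ] %in% members & cmb[2, ] %in% members,
        stringsAsFactors = FALSE)
    }
    covs <- with_seed(derive_seed(ep_seed, 5), anesthesia_record(
      sevoflurane_pct = stats::runif(1, 0.5, 3),
      midazolam_at_induction = stats::runif(1) < 0.5,
      propofol_at_induction = stats::runif(1) < 0.5,
      fentanyl_use = sample(c("none", "induction", "intervals"), 1),
      temperature_c = stats::rnorm(1, 36.3, 0.5),
      gas_carrier = sample(c("air", "NO", "neither"), 1),
      decadron_use = stats::runif(1) < 0.5,
      minutes_since_last_change = stats::runif(1, 2, 60)))
    epochs[[i]] <- epoch(eid, pid, trains, duration_s = dur,
                         covariates = covs)
  }
  units <- do.call(rbind, unit_rows)
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(patient_id = character(), epoch_id = character(),
               unit_a = character(), unit_b = character(),
               true_coupled = logical(), stringsAsFactors = FALSE)
  rownames(units) <- rownames(pairs) <- NULL
  list(session = spike_session(epochs), units = units, pairs = pairs)
}

#' Default 1.1 ms biphasic spike waveform template
#'
#' @param sampling_hz Sampling rate, Hz.
#' @param width_ms Template width in ms.
#' @param amplitude Peak amplitude (same units as the trace).
#' @return Numeric vector of template samples.
#' @export
spike_waveform_template <- function(sampling_hz = 29412, width_ms = 1.1,
                                    amplitude = 1) {
  nsamp <- max(3L, round(width_ms / 1000 * sampling_hz))
  if (nsamp %% 2L == 0L) nsamp <- nsamp + 1L  # odd length: single peak sample
  t <- seq(-1, 1, length.out = nsamp)
  # sharp monophasic negative deflection; no side lobes, so one spike
  # produces exactly one suprathreshold excursion anchored at its center
  w <- -exp(-t^2 / (2 * (1 / 6)^2))
  amplitude * w / max(abs(w))
}

#' Render a raw voltage trace from spike trains
#'
#' Gaussian noise plus a waveform template placed at each spike time, for
#' exercising the threshold detector.
#'
#' @param trains List of [spike_train()]s on one channel.
#' @param duration_s Trace duration, seconds.
#' @param noise_sd Noise SD (arbitrary units).
#' @param template Waveform template vector (see
#'   [spike_waveform_template()]).
#' @param sampling_hz Sampling rate, Hz (default 29412).
#' @param seed Optional seed.
#' @return List of class `voltage_trace`: `samples`, `sampling_hz`,
#'   `duration_s`.
#' @export
render_trace <- function(trains = list(), duration_s = 10, noise_sd = 1,
                         template = spike_waveform_template(sampling_hz,
                                                            amplitude = 10),
                         sampling_hz = 29412, seed = NULL) {
  if (sampling_hz <= 0) stopf("sampling_hz must be > 0")
  nsamp <- round(duration_s * sampling_hz)
  v <- with_seed(seed, stats::rnorm(nsamp, 0, noise_sd))
  half <- (length(template) - 1L) %/% 2L
  for (tr in trains) {
    if (length(tr$spike_times) && max(tr$spike_times) > duration_s)
      stopf("train extends beyond trace duration")
    for (t0 in tr$spike_times) {
      center <- round(t0 * sampling_hz) + 1L
      idx <- (center - half):(center - half + length(template) - 1L)
      ok <- idx >= 1L & idx <= nsamp
      v[idx[ok]] <- v[idx[ok]] + template[ok]
    }
  }
  structure(list(samples = v, sampling_hz = sampling_hz,
                 duration_s = duration_s), class = "voltage_trace")
}
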