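#' Threshold detection parameters
#'
#' Defaults follow the acquisition convention emulated here: events are
#' captured where the voltage falls outside +-2.8 SDs of the entire trace,
#' with a 1.1 ms capture window, at a 29412 Hz sampling rate.
#'
#' @param threshold_sd Threshold in multiples of the whole-trace SD (> 0).
#' @param window_ms Capture window length in ms (> 0).
#' @param sampling_hz Sampling rate in Hz.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(threshold_sd = 2.8, window_ms = 1.1,
                             sampling_hz = 29412) {
  if (threshold_sd <= 0) stopf("threshold_sd must be > 0")
  if (window_ms <= 0) stopf("window_ms must be > 0")
  if (sampling_hz <= 0) stopf("sampling_hz must be > 0")
  structure(list(threshold_sd = threshold_sd, window_ms = window_ms,
                 sampling_hz = sampling_hz), class = "detection_params")
}

#' Detect suprathreshold events on a voltage trace
#'
#' Flags samples where `|v|` exceeds `threshold_sd * SD(trace)`. A run of
#' consecutive suprathreshold samples counts as one excursion; the event is
#' anchored at the sample of largest absolute amplitude within the
#' excursion, and a snippet of `window_ms` centered on the anchor is cut
#' out (so a single action potential is never double-counted).
#'
#' @param trace A `voltage_trace` (see [render_trace()]) or numeric vector.
#' @param params A [detection_params()].
#' @return List: `times` (event times, s), `index` (anchor samples),
#'   `snippets` (matrix, one row per event), `threshold` (absolute
#'   threshold used).
#' @export
detect_events <- function(trace, params = detection_params()) {
  v <- if (inherits(trace, "voltage_trace")) trace$samples else as.numeric(trace)
  hz <- if (inherits(trace, "voltage_trace")) trace$sampling_hz else
    params$sampling_hz
  wlen <- max(3L, round(params$window_ms / 1000 * hz))
  if (length(v) < wlen) stopf("trace shorter than the capture window")
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stopf("zero-variance trace")
  thr <- params$threshold_sd * s
  over <- abs(v) > thr
  if (!any(over))
    return(list(times = numeric(), index = integer(),
                snippets = matrix(numeric(), 0, wlen), threshold = thr))
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  anchors <- mapply(function(a, b) a - 1L + which.max(abs(v[a:b])),
                    starts[keep], ends[keep])
  half <- (wlen - 1L) %/% 2L
  snips <- t(vapply(anchors, function(ix) {
    idx <- (ix - half):(ix - half + wlen - 1L)
    out <- rep(NA_real_, wlen)
    ok <- idx >= 1L & idx <= length(v)
    out[ok] <- v[idx[ok]]
    out
  }, numeric(wlen)))
  list(times = (anchors - 1L) / hz, index = as.integer(anchors),
       snippets = snips, threshold = thr)
}

#' Remove cross-channel duplicate spikes within an epoch
#'
#' The same physical action potential can be captured on two microwires
#' almost simultaneously. Scanning all spikes from all channels in global
#' time order, whenever a spike on a *different* channel follows the most
#' recently retained spike by less than `threshold_us`, the later spike is
#' deleted. Same-channel intervals are never touched. Exact cross-channel
#' ties delete the spike from the higher-numbered channel. The scan is
#' sequential, so in a chain at 0, 60 and 120 us on three channels the
#' middle spike is deleted and the outer two are kept. The operation is
#' idempotent.
#'
#' @param trains List of [spike_train()]s from one epoch.
#' @param threshold_us Duplicate threshold in microseconds (default 100).
#' @return The list of trains with duplicate spikes removed.
#' @export
remove_duplicate_spikes <- function(trains, threshold_us = 100) {
  if (!length(trains)) return(trains)
  thr <- threshold_us * 1e-6
  n_per <- vapply(trains, function(tr) length(tr$spike_times), 0L)
  if (sum(n_per) == 0L) return(trains)
  tt <- unlist(lapply(trains, `[[`, "spike_times"))
  src <- rep(seq_along(trains), n_per)
  ch <- vapply(trains, `[[`, 0L, "channel_id")[src]
  pos <- unlist(lapply(n_per, seq_len))
  ord <- order(tt, ch)  # ties: lower channel first, so it is retained
  tt <- tt[ord]; src <- src[ord]; ch <- ch[ord]; pos <- pos[ord]
  keep <- logical(length(tt))
  last_t <- -Inf; last_ch <- -1L
  for (i in seq_along(tt)) {
    if (ch[i] != last_ch && (tt[i] - last_t) < thr) {
      keep[i] <- FALSE
    } else {
      keep[i] <- TRUE
      last_t <- tt[i]; last_ch <- ch[i]
    }
  }
  for (k in seq_along(trains)) {
    sel <- src == k & keep
    trains[[k]]$spike_times <- sort(tt[sel])
  }
  trains
}

#' Apply duplicate-spike removal to every epoch of a session
#'
#' @param session A [spike_session()].
#' @param threshold_us Duplicate threshold in microseconds.
#' @return The session with deduplicated trains.
#' @export
dedup_session <- function(session, threshold_us = 100) {
  stopifnot(inherits(session, "spike_session"))
  session$epochs <- lapply(session$epochs, function(ep) {
    ep$trains <- remove_duplicate_spikes(ep$trains, threshold_us)
    ep
  })
  session
}
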