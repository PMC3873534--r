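#' Construct a spike train
#'
#' A spike train holds the sorted firing times of one isolated unit within
#' one recording epoch, together with the microwire channel it was recorded
#' on. Times are seconds relative to the epoch start. Unsorted input is
#' sorted on ingest; non-finite or negative times are rejected.
#'
#' @param unit_id Unit identifier (coerced to character).
#' @param channel_id Integer channel of origin, 1-8.
#' @param spike_times Numeric vector of spike times in seconds.
#' @param epoch_id Epoch identifier (coerced to character).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(unit_id, channel_id, spike_times, epoch_id = "e1") {
  if (length(channel_id) != 1L || is.na(channel_id) ||
      channel_id != as.integer(channel_id) || channel_id < 1 || channel_id > 8)
    stopf("channel_id must be a single integer in 1..8 (got %s)",
          paste(channel_id, collapse = ","))
  spike_times <- as.numeric(spike_times)
  if (anyNA(spike_times) || any(!is.finite(spike_times)))
    stopf("spike_times contains NA/NaN/Inf for unit '%s'", unit_id)
  if (any(spike_times < 0))
    stopf("spike time out of range (negative) for unit '%s'", unit_id)
  if (is.unsorted(spike_times)) spike_times <- sort(spike_times)
  structure(
    list(unit_id = as.character(unit_id),
         channel_id = as.integer(channel_id),
         spike_times = spike_times,
         epoch_id = as.character(epoch_id)),
    class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s (epoch %s, ch %d): %d spikes\n",
              x$unit_id, x$epoch_id, x$channel_id, length(x$spike_times)))
  invisible(x)
}

#' Construct an anesthesia covariate record
#'
#' Per-epoch anesthesia context used by [anesthesia_glm()]: sevoflurane
#' dose (percent of inhaled gas), induction-drug flags, fentanyl usage
#' category, core temperature, carrier gas, decadron flag, and minutes
#' since the last change in anesthetic management.
#'
#' @param sevoflurane_pct Percent sevoflurane in inhaled gas (>= 0).
#' @param midazolam_at_induction,propofol_at_induction,decadron_use Logical flags.
#' @param fentanyl_use One of "induction", "intervals", "none".
#' @param temperature_c Core temperature in degrees Celsius.
#' @param gas_carrier One of "air", "NO", "neither".
#' @param minutes_since_last_change Minutes since last anesthetic change (>= 0).
#' @return An object of class `anesthesia_record`.
#' @export
anesthesia_record <- function(sevoflurane_pct = 0,
                              midazolam_at_induction = FALSE,
                              propofol_at_induction = FALSE,
                              fentanyl_use = c("none", "induction", "intervals"),
                              temperature_c = 36.5,
                              gas_carrier = c("air", "NO", "neither"),
                              decadron_use = FALSE,
                              minutes_since_last_change = 0) {
  fentanyl_use <- match.arg(fentanyl_use)
  gas_carrier <- match.arg(gas_carrier)
  if (sevoflurane_pct < 0) stopf("sevoflurane_pct must be >= 0")
  if (minutes_since_last_change < 0)
    stopf("minutes_since_last_change must be >= 0")
  structure(
    list(sevoflurane_pct = as.numeric(sevoflurane_pct),
         midazolam_at_induction = isTRUE(midazolam_at_induction),
         propofol_at_induction = isTRUE(propofol_at_induction),
         fentanyl_use = fentanyl_use,
         temperature_c = as.numeric(temperature_c),
         gas_carrier = gas_carrier,
         decadron_use = isTRUE(decadron_use),
         minutes_since_last_change = as.numeric(minutes_since_last_change)),
    class = "anesthesia_record")
}

#' Construct a recording epoch
#'
#' One continuous recording period (default 300 s) at a fixed microwire
#' position: a set of spike trains plus patient context and optional
#' anesthesia covariates.
#'
#' @param epoch_id,patient_id Identifiers.
#' @param trains List of [spike_train()] objects. Their `epoch_id` fields
#'   are overwritten with `epoch_id`; unit ids must be unique.
#' @param duration_s Epoch duration in seconds (> 0).
#' @param covariates Optional [anesthesia_record()].
#' @return An object of class `epoch`.
#' @export
epoch <- function(epoch_id, patient_id, trains = list(), duration_s = 300,
                  covariates = NULL) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stopf("duration_s must be > 0")
  if (!is.null(covariates) && !inherits(covariates, "anesthesia_record"))
    stopf("covariates must be an anesthesia_record or NULL")
  trains <- lapply(trains, function(tr) {
    if (!inherits(tr, "spike_train")) stopf("trains must be spike_train objects")
    if (length(tr$spike_times) && max(tr$spike_times) > duration_s)
      stopf("spike time out of range (> duration %g s) for unit '%s'",
            duration_s, tr$unit_id)
    tr$epoch_id <- as.character(epoch_id)
    tr
  })
  ids <- vapply(trains, `[[`, "", "unit_id")
  if (anyDuplicated(ids))
    stopf("duplicate unit_id within epoch '%s': %s", epoch_id,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(trains) <- ids
  structure(
    list(epoch_id = as.character(epoch_id),
         patient_id = as.character(patient_id),
         duration_s = as.numeric(duration_s),
         trains = trains,
         covariates = covariates),
    class = "epoch")
}

#' Construct a recording session
#'
#' A session is a collection of epochs across patients. (patient, epoch)
#' id pairs must be unique.
#'
#' @param epochs List of [epoch()] objects.
#' @return An object of class `spike_session`.
#' @export
spike_session <- function(epochs = list()) {
  for (ep in epochs)
    if (!inherits(ep, "epoch")) stopf("epochs must be epoch objects")
  keys <- vapply(epochs, function(e) paste(e$patient_id, e$epoch_id, sep = "\r"), "")
  if (anyDuplicated(keys))
    stopf("duplicate (patient_id, epoch_id) in session")
  structure(list(epochs = epochs), class = "spike_session")
}

#' @export
print.spike_session <- function(x, ...) {
  tab <- unit_count_table(x)
  cat(sprintf("<spike_session> %d patients, %d epochs, %d units\n",
              length(unique(tab$patient_id)), nrow(tab), sum(tab$n_units)))
  invisible(x)
}

#' Units-per-epoch table
#'
#' One row per epoch with the number of sorted units it contains, in the
#' layout of a per-subject unit-count table.
#'
#' @param session A [spike_session()].
#' @return `data.frame` with columns `patient_id`, `epoch_id`, `n_units`.
#' @export
unit_count_table <- function(session) {
  stopifnot(inherits(session, "spike_session"))
  if (!length(session$epochs))
    return(data.frame(patient_id = character(), epoch_id = character(),
                      n_units = integer(), stringsAsFactors = FALSE))
  data.frame(
    patient_id = vapply(session$epochs, `[[`, "", "patient_id"),
    epoch_id = vapply(session$epochs, `[[`, "", "epoch_id"),
    n_units = vapply(session$epochs, function(e) length(e$trains), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
}

cov_to_list <- function(cv) {
  if (is.null(cv)) NULL else unclass(cv)
}
cov_from_list <- function(lst) {
  if (is.null(lst)) return(NULL)
  do.call(anesthesia_record, lst)
}

session_to_tables <- function(session) {
  rows <- lapply(session$epochs, function(e) {
    if (!length(e$trains))
      return(NULL)
    do.call(rbind, lapply(e$trains, function(tr) {
      data.frame(patient_id = e$patient_id, epoch_id = e$epoch_id,
                 unit_id = tr$unit_id, channel_id = tr$channel_id,
                 spike_time_s = tr$spike_times, stringsAsFactors = FALSE)
    }))
  })
  spikes <- do.call(rbind, c(rows, list(
    data.frame(patient_id = character(), epoch_id = character(),
               unit_id = character(), channel_id = integer(),
               spike_time_s = numeric(), stringsAsFactors = FALSE))))
  rownames(spikes) <- NULL
  meta <- lapply(session$epochs, function(e) {
    units <- lapply(unname(e$trains), function(tr)
      list(unit_id = tr$unit_id, channel_id = tr$channel_id))
    list(patient_id = e$patient_id, epoch_id = e$epoch_id,
         duration_s = e$duration_s, covariates = cov_to_list(e$covariates),
         units = units)
  })
  list(spikes = spikes, meta = unname(meta))
}

session_from_tables <- function(spikes, meta) {
  epochs <- lapply(meta, function(m) {
    sel <- spikes$patient_id == m$patient_id & spikes$epoch_id == m$epoch_id
    sub <- spikes[sel, , drop = FALSE]
    if (any(!is.finite(sub$spike_time_s)))
      stopf("non-finite spike time in epoch '%s'", m$epoch_id)
    if (any(sub$spike_time_s < 0))
      stopf("spike time out of range (negative) in epoch '%s'", m$epoch_id)
    units <- m$units %||% list()
    trains <- lapply(units, function(u) {
      usel <- sub$unit_id == u$unit_id
      spike_train(u$unit_id, u$channel_id, sub$spike_time_s[usel], m$epoch_id)
    })
    # units present in the spike table but missing from metadata
    extra <- setdiff(unique(sub$unit_id),
                     vapply(units, function(u) as.character(u$unit_id), ""))
    trains <- c(trains, lapply(extra, function(uid) {
      usel <- sub$unit_id == uid
      spike_train(uid, sub$channel_id[usel][1], sub$spike_time_s[usel],
                  m$epoch_id)
    }))
    epoch(m$epoch_id, m$patient_id, trains, duration_s = m$duration_s,
          covariates = cov_from_list(m$covariates))
  })
  spike_session(epochs)
}

meta_path <- function(path) paste0(sub("\\.[A-Za-z0-9]+$", "", path), "_meta.json")

#' Write a session to disk
#'
#' CSV format is a long spike table (`patient_id`, `epoch_id`, `unit_id`,
#' `channel_id`, `spike_time_s` with microsecond precision) plus a JSON
#' sidecar `<stem>_meta.json` holding epoch durations, unit/channel maps
#' and anesthesia covariates. JSON format stores everything in one file.
#' Output is byte-stable for a fixed session.
#'
#' @param session A [spike_session()].
#' @param path Output file path.
#' @param format "csv" or "json".
#' @return `path`, invisibly.
#' @seealso [load_session()]
#' @export
write_session <- function(session, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(session, "spike_session"))
  tabs <- session_to_tables(session)
  tabs$spikes$spike_time_s <- sprintf("%.6f", tabs$spikes$spike_time_s)
  if (format == "csv") {
    utils::write.csv(tabs$spikes, path, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(tabs$meta, meta_path(path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    jsonlite::write_json(list(spikes = tabs$spikes, meta = tabs$meta), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Load a session from disk
#'
#' Reads files produced by [write_session()]. Spike times are sorted on
#' ingest; NaN or negative times, or duplicate unit ids within an epoch,
#' are errors.
#'
#' @param path File path.
#' @param format "csv" or "json".
#' @return A validated [spike_session()].
#' @export
load_session <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "csv") {
    spikes <- utils::read.csv(path, stringsAsFactors = FALSE,
                              colClasses = c(spike_time_s = "numeric"))
    mp <- meta_path(path)
    if (!file.exists(mp)) stopf("metadata sidecar not found: %s", mp)
    meta <- jsonlite::read_json(mp, simplifyVector = FALSE)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = FALSE)
    meta <- obj$meta
    sp <- obj$spikes
    spikes <- data.frame(
      patient_id = vapply(sp, function(r) as.character(r$patient_id), ""),
      epoch_id = vapply(sp, function(r) as.character(r$epoch_id), ""),
      unit_id = vapply(sp, function(r) as.character(r$unit_id), ""),
      channel_id = vapply(sp, function(r) as.integer(r$channel_id), 0L),
      spike_time_s = vapply(sp, function(r) as.numeric(r$spike_time_s), 0),
      stringsAsFactors = FALSE)
  }
  need <- c("patient_id", "epoch_id", "unit_id", "channel_id", "spike_time_s")
  if (!all(need %in% names(spikes)))
    stopf("parse failure: missing columns %s",
          paste(setdiff(need, names(spikes)), collapse = ", "))
  spikes$patient_id <- as.character(spikes$patient_id)
  spikes$epoch_id <- as.character(spikes$epoch_id)
  spikes$unit_id <- as.character(spikes$unit_id)
  session_from_tables(spikes, meta)
}
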