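#' Electrode montage
#'
#' Describes the recording geometry: ordered electrode labels, reference and
#' ground positions, and the sampling rate. The default montage is the
#' eight-channel parieto-occipital set used by the hand-orthosis interface
#' (Fz, Cz, P3, Pz, P4, PO7, PO8, Oz; reference on the right earlobe, ground
#' at AFz) sampled at 256 Hz.
#'
#' @param channel_names Character vector of unique electrode labels.
#' @param reference Reference electrode label.
#' @param ground Ground electrode label.
#' @param sampling_rate Sampling rate in Hz (positive).
#' @return An object of class `bmi_montage`.
#' @export
montage <- function(channel_names, reference, ground, sampling_rate) {
  if (anyDuplicated(channel_names)) {
    stop_validation("montage channel names must be unique")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop_parameter("sampling_rate must be a positive number")
  }
  structure(
    list(
      channel_names = as.character(channel_names),
      reference = reference,
      ground = ground,
      sampling_rate = sampling_rate
    ),
    class = "bmi_montage"
  )
}

#' @rdname montage
#' @export
default_montage <- function() {
  montage(
    channel_names = c("Fz", "Cz", "P3", "Pz", "P4", "PO7", "PO8", "Oz"),
    reference = "right earlobe",
    ground = "AFz",
    sampling_rate = 256
  )
}

# Recognized experimental conditions for stimulus events.
CONDITION_TAGS <- c("calibration", "online_without_orthosis",
                    "online_with_orthosis")

# Event table columns, in serialization order.
EVENT_COLUMNS <- c("onset_sample", "option_id", "run_id", "cued_target",
                   "condition_tag")

#' Construct a stimulus event table
#'
#' Events mark flash onsets of the oddball stimulation. `onset_sample` is a
#' 0-based index into the signal; `option_id` identifies which of the `n_c`
#' flashing circles was highlighted; `cued_target` is the option the subject
#' was instructed to attend (NA outside cued runs).
#'
#' @param onset_sample Integer vector, 0-based sample indices.
#' @param option_id Integer vector in `[0, n_c)`.
#' @param run_id Integer run identifiers.
#' @param cued_target Integer option ids or NA.
#' @param condition_tag One of `"calibration"`, `"online_without_orthosis"`,
#'   `"online_with_orthosis"` (recycled).
#' @return A `data.frame` with the five standard event columns, sorted by
#'   onset.
#' @export
stimulus_events <- function(onset_sample, option_id, run_id,
                            cued_target = NA_integer_,
                            condition_tag = "calibration") {
  ev <- data.frame(
    onset_sample = as.integer(onset_sample),
    option_id = as.integer(option_id),
    run_id = as.integer(run_id),
    cued_target = as.integer(cued_target),
    condition_tag = as.character(condition_tag),
    stringsAsFactors = FALSE
  )
  validate_event_columns(ev)
  ev[order(ev$onset_sample), , drop = FALSE]
}

validate_event_columns <- function(events) {
  missing <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing)) {
    stop_format(sprintf("events table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  bad <- !events$condition_tag %in% CONDITION_TAGS
  if (any(bad)) {
    stop_validation(sprintf(
      "unknown condition_tag '%s' in event row %d",
      events$condition_tag[which(bad)[1]], which(bad)[1]))
  }
  invisible(events)
}

#' EEG recording container
#'
#' Bundles a channels-by-samples signal matrix (amplitudes in microvolts),
#' the montage, the stimulus event log, and free-form metadata. Events are
#' kept sorted by onset.
#'
#' @param signals Numeric matrix, channels x samples, in microvolts.
#' @param montage A `bmi_montage`; its channel count must match `nrow(signals)`.
#' @param events Event table (see [stimulus_events()]); may have zero rows.
#' @param metadata Named list of free-form metadata.
#' @return An object of class `bmi_recording`.
#' @export
recording <- function(signals, montage = default_montage(),
                      events = empty_events(), metadata = list()) {
  if (!is.matrix(signals) || !is.numeric(signals)) {
    stop_format("signals must be a numeric matrix (channels x samples)")
  }
  if (nrow(signals) != length(montage$channel_names)) {
    stop_format(sprintf(
      "signal has %d rows but montage lists %d channels",
      nrow(signals), length(montage$channel_names)))
  }
  validate_event_columns(events)
  events <- events[order(events$onset_sample), , drop = FALSE]
  rownames(events) <- NULL
  rownames(signals) <- montage$channel_names
  structure(
    list(signals = signals, montage = montage, events = events,
         metadata = metadata),
    class = "bmi_recording"
  )
}

#' @rdname recording
#' @export
empty_events <- function() {
  stimulus_events(integer(0), integer(0), integer(0), integer(0),
                  character(0))
}

#' @export
print.bmi_recording <- function(x, ...) {
  fs <- x$montage$sampling_rate
  cat(sprintf("<bmi_recording> %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$signals), ncol(x$signals), ncol(x$signals) / fs, fs))
  cat(sprintf("  channels: %s\n",
              paste(x$montage$channel_names, collapse = ", ")))
  cat(sprintf("  events: %d\n", nrow(x$events)))
  invisible(x)
}

#' Number of samples in the post-stimulus epoch window
#'
#' The post-stimulus window is 800 ms by default; its length in samples is
#' `floor(epoch_ms / 1000 * sampling_rate)` (204 at 256 Hz). Windows are
#' half-open `[onset, onset + n_t)` with 0-based onsets.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param epoch_ms Window length in milliseconds.
#' @return Integer sample count.
#' @export
epoch_samples <- function(sampling_rate = 256, epoch_ms = 800) {
  as.integer(floor(epoch_ms / 1000 * sampling_rate))
}

validate_event_windows <- function(events, n_samples, n_t, n_c = 6) {
  if (!nrow(events)) return(invisible(events))
  over <- which(events$onset_sample + n_t > n_samples |
                  events$onset_sample < 0)
  if (length(over)) {
    stop_validation(sprintf(
      paste0("event row %d: onset_sample %d leaves no room for a %d-sample ",
             "epoch in a %d-sample signal"),
      over[1], events$onset_sample[over[1]], n_t, n_samples))
  }
  bad_opt <- which(events$option_id < 0 | events$option_id >= n_c)
  if (length(bad_opt)) {
    stop_validation(sprintf("event row %d: option_id %d outside [0, %d)",
                            bad_opt[1], events$option_id[bad_opt[1]], n_c))
  }
  invisible(events)
}

#' Read a session bundle
#'
#' Reads a signal file (headered CSV, rows = samples, columns = channels,
#' values in microvolts) and a TSV event log into a [recording()]. A JSON
#' metadata sidecar is read when present. Events are re-sorted by onset, and
#' every event must leave room for a full post-stimulus window. EDF input is
#' not supported in this build; CSV is the interchange format.
#'
#' @param signal_path Path to the CSV signal matrix.
#' @param events_path Path to the TSV event log.
#' @param montage Expected montage; channel count and names are checked
#'   against the CSV header.
#' @param metadata_path Optional JSON sidecar; defaults to
#'   `<signal_path>.json` when that file exists.
#' @param epoch_ms Post-stimulus window used for event validation.
#' @param n_c Number of flashing options.
#' @return A `bmi_recording`.
#' @export
read_session <- function(signal_path, events_path,
                         montage = default_montage(),
                         metadata_path = NULL, epoch_ms = 800, n_c = 6) {
  if (!file.exists(signal_path)) {
    stop_io(sprintf("signal file not found: %s", signal_path))
  }
  if (!file.exists(events_path)) {
    stop_io(sprintf("events file not found: %s", events_path))
  }
  sig <- data.table::fread(signal_path, header = TRUE, sep = ",",
                           data.table = FALSE)
  if (ncol(sig) != length(montage$channel_names)) {
    stop_format(sprintf(
      "signal file has %d columns but montage lists %d channels",
      ncol(sig), length(montage$channel_names)))
  }
  if (!identical(names(sig), montage$channel_names)) {
    stop_format(sprintf(
      "signal header (%s) does not match montage channels (%s)",
      paste(names(sig), collapse = ","),
      paste(montage$channel_names, collapse = ",")))
  }
  signals <- t(as.matrix(sig))

  ev <- data.table::fread(events_path, header = TRUE, sep = "\t",
                          data.table = FALSE, na.strings = "NA",
                          colClasses = list(character = "condition_tag"))
  if (!nrow(ev)) {
    events <- empty_events()
  } else {
    validate_event_columns(ev)
    events <- stimulus_events(ev$onset_sample, ev$option_id, ev$run_id,
                              ev$cued_target, ev$condition_tag)
  }
  n_t <- epoch_samples(montage$sampling_rate, epoch_ms)
  validate_event_windows(events, ncol(signals), n_t, n_c)

  if (is.null(metadata_path)) {
    candidate <- paste0(signal_path, ".json")
    if (file.exists(candidate)) metadata_path <- candidate
  }
  metadata <- if (!is.null(metadata_path) && file.exists(metadata_path)) {
    jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  } else {
    list()
  }
  recording(signals, montage, events, metadata)
}

#' Write a session bundle
#'
#' Writes the signal matrix as headered CSV (rows = samples, columns =
#' channels, microvolts), the events as TSV with the fixed column order
#' `onset_sample, option_id, run_id, cued_target, condition_tag` (missing
#' cued targets serialized as `NA`), and the metadata as a JSON sidecar
#' `<signal_path>.json` when non-empty.
#'
#' @param rec A `bmi_recording` with finite signal values.
#' @param signal_path Output CSV path.
#' @param events_path Output TSV path.
#' @param metadata_path Optional JSON path (default `<signal_path>.json`).
#' @return Invisibly, the paths written.
#' @export
write_session <- function(rec, signal_path, events_path,
                          metadata_path = NULL) {
  stopifnot(inherits(rec, "bmi_recording"))
  if (!all(is.finite(rec$signals))) {
    stop_validation("signals contain non-finite values; refusing to write")
  }
  sig <- as.data.frame(t(rec$signals))
  names(sig) <- rec$montage$channel_names
  ok <- tryCatch({
    data.table::fwrite(sig, signal_path, sep = ",")
    data.table::fwrite(rec$events[, EVENT_COLUMNS, drop = FALSE],
                       events_path, sep = "\t", na = "NA", quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_io(conditionMessage(ok))
  paths <- c(signal = signal_path, events = events_path)
  if (length(rec$metadata)) {
    if (is.null(metadata_path)) metadata_path <- paste0(signal_path, ".json")
    jsonlite::write_json(rec$metadata, metadata_path, auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, metadata = metadata_path)
  }
  invisible(paths)
}
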