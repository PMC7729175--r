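#' Band-pass specification
#'
#' The system uses three fixed analysis bands: 4-14 Hz (classification
#' band), 20-40 Hz (muscle-artifact band), and 4-40 Hz (broadband for epoch
#' validation and ERP display).
#'
#' @param low_hz,high_hz Band edges in Hz, `0 < low < high`.
#' @return Object of class `bmi_band`.
#' @export
band_spec <- function(low_hz, high_hz) {
  if (!(low_hz > 0 && high_hz > low_hz)) {
    stop_parameter("band edges must satisfy 0 < low_hz < high_hz")
  }
  structure(list(low_hz = low_hz, high_hz = high_hz), class = "bmi_band")
}

#' @rdname band_spec
#' @export
system_bands <- function() {
  list(band_4_14 = band_spec(4, 14),
       band_20_40 = band_spec(20, 40),
       band_4_40 = band_spec(4, 40))
}

# Hamming-window linear-phase FIR band-pass. Caching keyed on
# (order, low, high, fs) avoids redesigning the same filter per channel.
.fir_cache <- new.env(parent = emptyenv())

design_fir <- function(band, sampling_rate, order = 256) {
  nyq <- sampling_rate / 2
  if (band$high_hz >= nyq) {
    stop_parameter(sprintf(
      "band upper edge %g Hz violates the Nyquist limit %g Hz",
      band$high_hz, nyq))
  }
  key <- sprintf("%d|%g|%g|%g", order, band$low_hz, band$high_hz,
                 sampling_rate)
  if (!is.null(.fir_cache[[key]])) return(.fir_cache[[key]])
  b <- signal::fir1(order, c(band$low_hz, band$high_hz) / nyq,
                    type = "pass", window = signal::hamming(order + 1))
  .fir_cache[[key]] <- as.numeric(b)
  .fir_cache[[key]]
}

#' Band-pass filter a recording
#'
#' Filters every channel with a causal linear-phase FIR band-pass (Hamming
#' window, order 256 at 256 Hz) and compensates the constant group delay of
#' `order/2` samples by shifting the output back, so that epoch windows stay
#' stimulus-locked. The trailing `order/2` samples, for which no input is
#' available after the shift, are zero.
#'
#' @param rec A `bmi_recording`.
#' @param band A `bmi_band` within the Nyquist limit.
#' @param order FIR filter order (even).
#' @return A `bmi_recording` with filtered signals; montage and events are
#'   unchanged and the band is noted in the metadata.
#' @export
filter_recording <- function(rec, band, order = 256) {
  stopifnot(inherits(rec, "bmi_recording"), inherits(band, "bmi_band"))
  b <- design_fir(band, rec$montage$sampling_rate, order)
  delay <- order %/% 2
  n <- ncol(rec$signals)
  filtered <- rec$signals
  for (e in seq_len(nrow(filtered))) {
    y <- as.numeric(signal::filter(b, 1, rec$signals[e, ]))
    if (delay > 0 && n > delay) {
      y <- c(y[(delay + 1):n], numeric(delay))
    }
    filtered[e, ] <- y
  }
  out <- rec
  out$signals <- filtered
  out$metadata$band <- c(band$low_hz, band$high_hz)
  out
}

#' @rdname filter_recording
#' @param bands Named list of `bmi_band`s (default the three system bands).
#' @return `filter_bands()`: named list of filtered recordings.
#' @export
filter_bands <- function(rec, bands = system_bands(), order = 256) {
  lapply(bands, function(b) filter_recording(rec, b, order))
}

#' Extract one flash epoch from band-filtered recordings
#'
#' Slices the half-open window `[onset, onset + n_t)` (0-based onset, 800 ms
#' so `n_t = 204` at 256 Hz) out of the three band-filtered signals of a
#' single flashing event.
#'
#' @param filtered Named list with elements `band_4_14`, `band_20_40`,
#'   `band_4_40` as produced by [filter_bands()].
#' @param event One-row event (a list or single-row data.frame with
#'   `onset_sample` etc.).
#' @param epoch_ms Post-stimulus window in ms.
#' @return Object of class `bmi_epoch` holding the three channels-by-`n_t`
#'   matrices and the source event.
#' @export
extract_epoch <- function(filtered, event, epoch_ms = 800) {
  req <- c("band_4_14", "band_20_40", "band_4_40")
  if (!all(req %in% names(filtered))) {
    stop_shape("filtered must contain recordings band_4_14, band_20_40, band_4_40")
  }
  fs <- filtered$band_4_40$montage$sampling_rate
  n_t <- epoch_samples(fs, epoch_ms)
  onset <- as.integer(event$onset_sample)
  n <- ncol(filtered$band_4_40$signals)
  if (onset < 0 || onset + n_t > n) {
    stop_range(sprintf(
      "epoch window [%d, %d) overruns the %d-sample recording",
      onset, onset + n_t, n))
  }
  cols <- (onset + 1):(onset + n_t)
  structure(
    list(
      X_4_14 = filtered$band_4_14$signals[, cols, drop = FALSE],
      X_20_40 = filtered$band_20_40$signals[, cols, drop = FALSE],
      X_4_40 = filtered$band_4_40$signals[, cols, drop = FALSE],
      event = as.list(event),
      n_t = n_t
    ),
    class = "bmi_epoch"
  )
}

#' Epoch quality validation
#'
#' Computes, per channel of the broadband (4-40 Hz) epoch, the peak-to-peak
#' voltage, the sample standard deviation (n-1 denominator), and the
#' 20-40 Hz / 4-40 Hz power ratio, and flags the epoch as an artifact when
#' any channel reaches `v_pp >= 200` uV, `sigma >= 50` uV, or
#' `ratio >= 0.7`. A zero broadband power denominator (dead channel or
#' disconnect) also yields the artifact verdict.
#'
#' @param epoch A `bmi_epoch`.
#' @param vpp_max,sigma_max,ratio_max Rejection thresholds (microvolts,
#'   microvolts, dimensionless).
#' @return Object of class `bmi_quality`: per-channel `v_pp`, `sigma`,
#'   `power_ratio` (NaN when degenerate) and `verdict` of `"valid"` or
#'   `"artifact"`.
#' @export
assess_quality <- function(epoch, vpp_max = 200, sigma_max = 50,
                           ratio_max = 0.7) {
  stopifnot(inherits(epoch, "bmi_epoch"))
  X <- epoch$X_4_40
  v_pp <- apply(X, 1, max) - apply(X, 1, min)
  sigma <- apply(X, 1, stats::sd)
  p_broad <- rowSums(X^2)
  p_high <- rowSums(epoch$X_20_40^2)
  degenerate <- p_broad == 0
  power_ratio <- ifelse(degenerate, NaN, p_high / p_broad)
  artifact <- any(v_pp >= vpp_max) || any(sigma >= sigma_max) ||
    any(degenerate) || any(power_ratio[!degenerate] >= ratio_max)
  structure(
    list(v_pp = v_pp, sigma = sigma, power_ratio = power_ratio,
         verdict = if (artifact) "artifact" else "valid"),
    class = "bmi_quality"
  )
}

#' Decimate a validated epoch
#'
#' Takes every fourth sample of the 4-14 Hz epoch matrix, starting at the
#' first sample (phase 0), yielding `ceil(n_t / 4)` = 51 time points at the
#' default geometry. The 4-14 Hz band lies far below the post-decimation
#' Nyquist frequency (32 Hz), so no additional anti-alias filtering is
#' applied. Downsampling an artifact-flagged epoch is a contract violation:
#' callers must validate first.
#'
#' @param epoch A `bmi_epoch`.
#' @param factor Decimation factor.
#' @param quality Optional pre-computed [assess_quality()] result; computed
#'   here when omitted.
#' @return Object of class `bmi_depoch` with matrix `Y` (channels x
#'   `n_t_hat`) and the source event.
#' @export
downsample_epoch <- function(epoch, factor = 4, quality = NULL) {
  stopifnot(inherits(epoch, "bmi_epoch"))
  if (is.null(quality)) quality <- assess_quality(epoch)
  if (quality$verdict != "valid") {
    stop_contract("downsample_epoch() called on an artifact-flagged epoch")
  }
  idx <- seq(1, epoch$n_t, by = factor)
  structure(
    list(Y = epoch$X_4_14[, idx, drop = FALSE],
         n_t_hat = length(idx),
         event = epoch$event),
    class = "bmi_depoch"
  )
}
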