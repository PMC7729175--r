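#' Simulation parameters for synthetic oddball EEG
#'
#' The generator emulates the statistical structure the pipeline assumes:
#' a stimulus-locked evoked deflection added on target flashes (Gaussian-
#' windowed positive peak, default 5 uV at 350 ms latency with 120 ms FWHM,
#' plus an optional early negativity at 220 ms weighted toward
#' parieto-occipital channels), a 1/f-shaped Gaussian background with an
#' alpha-band bump and inter-channel correlation 0.3, and occasional
#' high-amplitude artifact bursts. A burst is an EMG-like 30 Hz tone under a
#' raised-cosine envelope (peak 300 uV, 200 ms): the in-band tone is what
#' makes the burst visible to the band-limited epoch validator, tripping
#' both the peak-to-peak and the 20-40 Hz power-ratio rejection rules. The
#' topography default emphasizes the centro-parietal channels (Cz, Pz). The
#' default background level (4 uV) emulates a low-noise recording of an
#' attentive subject, i.e. the high-signal-to-noise end of the study
#' conditions.
#'
#' @param erp_amplitude Positive peak amplitude in microvolts.
#' @param erp_latency_ms,erp_width_ms Peak latency and FWHM in ms.
#' @param early_negativity List with `amplitude`, `latency_ms`, `width_ms`,
#'   or NULL to disable.
#' @param topography Per-channel gain of the positive peak (length 8).
#' @param neg_topography Per-channel gain of the early negativity.
#' @param noise_sd Background standard deviation per channel, microvolts.
#' @param noise_exponent 1/f amplitude-spectrum exponent.
#' @param alpha_gain Relative gain of the 10 Hz spectral bump.
#' @param channel_correlation Pairwise background correlation.
#' @param artifact_rate_per_min Expected artifact bursts per minute.
#' @param artifact_amplitude_uv,artifact_duration_ms Burst envelope peak and
#'   duration.
#' @param artifact_tone_hz Carrier frequency of the burst.
#' @return Named list of class `bmi_sim_params`.
#' @export
sim_params <- function(erp_amplitude = 5,
                       erp_latency_ms = 350,
                       erp_width_ms = 120,
                       early_negativity = list(amplitude = 2.5,
                                               latency_ms = 220,
                                               width_ms = 80),
                       topography = c(0.6, 0.9, 0.8, 1.0, 0.8, 0.5, 0.5, 0.6),
                       neg_topography = c(0.2, 0.3, 0.4, 0.4, 0.4,
                                          1.0, 1.0, 0.8),
                       noise_sd = 4,
                       noise_exponent = 1,
                       alpha_gain = 0.5,
                       channel_correlation = 0.3,
                       artifact_rate_per_min = 2,
                       artifact_amplitude_uv = 300,
                       artifact_duration_ms = 200,
                       artifact_tone_hz = 30) {
  if (erp_amplitude < 0) stop_parameter("erp_amplitude must be >= 0")
  structure(
    list(erp_amplitude = erp_amplitude, erp_latency_ms = erp_latency_ms,
         erp_width_ms = erp_width_ms, early_negativity = early_negativity,
         topography = topography, neg_topography = neg_topography,
         noise_sd = noise_sd, noise_exponent = noise_exponent,
         alpha_gain = alpha_gain, channel_correlation = channel_correlation,
         artifact_rate_per_min = artifact_rate_per_min,
         artifact_amplitude_uv = artifact_amplitude_uv,
         artifact_duration_ms = artifact_duration_ms,
         artifact_tone_hz = artifact_tone_hz),
    class = "bmi_sim_params"
  )
}

# 1/f-shaped correlated Gaussian background, channels in columns.
colored_noise <- function(n_samples, n_channels, sampling_rate, params) {
  W <- matrix(stats::rnorm(n_samples * n_channels), n_samples, n_channels)
  f <- seq(0, n_samples - 1) / n_samples * sampling_rate
  f_act <- pmin(f, sampling_rate - f)
  gain <- pmax(f_act, 1)^(-params$noise_exponent)
  gain <- gain * (1 + params$alpha_gain * exp(-(f_act - 10)^2 / (2 * 2^2)))
  Wf <- stats::mvfft(W) * gain
  X <- Re(stats::mvfft(Wf, inverse = TRUE)) / n_samples
  rho <- params$channel_correlation
  R <- matrix(rho, n_channels, n_channels)
  diag(R) <- 1
  X <- X %*% chol(R)
  sds <- apply(X, 2, stats::sd)
  sweep(X, 2, ifelse(sds > 0, sds, 1), "/") * params$noise_sd
}

# Channels x n_t evoked-response template added at each target flash onset.
erp_template_matrix <- function(params, sampling_rate, n_t) {
  t_ms <- (seq_len(n_t) - 1) * 1000 / sampling_rate
  sd_pos <- params$erp_width_ms / 2.355
  pos <- params$erp_amplitude *
    exp(-(t_ms - params$erp_latency_ms)^2 / (2 * sd_pos^2))
  M <- outer(params$topography, pos)
  if (!is.null(params$early_negativity) && params$erp_amplitude > 0) {
    en <- params$early_negativity
    sd_neg <- en$width_ms / 2.355
    neg <- -en$amplitude * exp(-(t_ms - en$latency_ms)^2 / (2 * sd_neg^2))
    M <- M + outer(params$neg_topography, neg)
  }
  M
}

# Raised-cosine artifact bursts; returns burst onset samples (may be empty).
draw_artifact_onsets <- function(n_samples, sampling_rate, params) {
  dur_min <- n_samples / sampling_rate / 60
  n_art <- stats::rpois(1, params$artifact_rate_per_min * dur_min)
  if (n_art == 0) return(integer(0))
  sort(sample.int(n_samples, n_art))
}

artifact_burst <- function(sampling_rate, params) {
  n_burst <- max(2L, round(params$artifact_duration_ms / 1000 *
                             sampling_rate))
  envelope <- params$artifact_amplitude_uv / 2 *
    (1 - cos(2 * pi * seq(0, 1, length.out = n_burst)))
  t <- (seq_len(n_burst) - 1) / sampling_rate
  list(wave = envelope * sin(2 * pi * params$artifact_tone_hz * t),
       envelope = envelope, n = n_burst)
}

add_artifacts <- function(signals, onsets, sampling_rate, params) {
  if (!length(onsets)) return(signals)
  b <- artifact_burst(sampling_rate, params)
  burst <- b$wave
  n_burst <- b$n
  n <- ncol(signals)
  for (o in onsets) {
    idx <- o:min(o + n_burst - 1L, n)
    signals[, idx] <- signals[, idx] +
      rep(burst[seq_along(idx)], each = nrow(signals))
  }
  signals
}

synth_session_signal <- function(n_samples, events, params, montage, seed) {
  n_e <- length(montage$channel_names)
  fs <- montage$sampling_rate
  old <- get_rng_state()
  on.exit(restore_rng_state(old))

  set.seed(substream_seed(seed, 4L))  # noise substream
  signals <- t(colored_noise(n_samples, n_e, fs, params))

  n_t <- epoch_samples(fs, 800)
  if (params$erp_amplitude > 0 && nrow(events)) {
    M <- erp_template_matrix(params, fs, n_t)
    tgt <- which(!is.na(events$cued_target) &
                   events$option_id == events$cued_target)
    for (i in tgt) {
      cols <- (events$onset_sample[i] + 1):(events$onset_sample[i] + n_t)
      cols <- cols[cols <= n_samples]
      signals[, cols] <- signals[, cols] + M[, seq_along(cols), drop = FALSE]
    }
  }

  set.seed(substream_seed(seed, 5L))  # artifact substream
  art_onsets <- draw_artifact_onsets(n_samples, fs, params)
  signals <- add_artifacts(signals, art_onsets, fs, params)
  list(signals = signals, artifact_onsets = art_onsets)
}

# TRUE for events whose epoch window contains burst envelope >= 100 uV, the
# level at which the in-band peak-to-peak reaches the 200 uV rejection
# threshold (the tone swings +/- the envelope).
flag_artifact_events <- function(events, artifact_onsets, sampling_rate,
                                 params, n_t, envelope_min = 100) {
  if (!length(artifact_onsets) || !nrow(events)) {
    return(rep(FALSE, nrow(events)))
  }
  b <- artifact_burst(sampling_rate, params)
  hot <- which(b$envelope >= envelope_min)
  if (!length(hot)) return(rep(FALSE, nrow(events)))
  hot_lo <- min(hot); hot_hi <- max(hot)
  vapply(seq_len(nrow(events)), function(i) {
    a <- events$onset_sample[i]; z <- a + n_t - 1
    any(artifact_onsets + hot_lo - 1 <= z & artifact_onsets + hot_hi - 1 >= a)
  }, logical(1))
}

#' Simulate a calibration session
#'
#' Synthesizes the continuous eight-channel recording of a calibration
#' schedule: correlated 1/f background noise, the evoked-response template
#' added at every flash of the cued option, and Poisson-scheduled artifact
#' bursts. All randomness derives from `seed` through named substreams
#' (schedule, noise, artifacts), so the session is fully reproducible.
#'
#' @param schedule A [build_schedule()] result.
#' @param params See [sim_params()].
#' @param seed Integer session seed.
#' @return Object of class `bmi_sim_session`: `recording` and
#'   `ground_truth` (per-event class, artifact flags, artifact onsets).
#' @export
simulate_calibration <- function(schedule, params = sim_params(), seed = 1) {
  stopifnot(inherits(schedule, "bmi_schedule"))
  mont <- default_montage()
  mont$sampling_rate <- schedule$sampling_rate
  fs <- mont$sampling_rate
  n_samples <- as.integer(ceiling(schedule$total_duration_s * fs))
  events <- schedule$events
  syn <- synth_session_signal(n_samples, events, params, mont, seed)
  n_t <- epoch_samples(fs, 800)
  gt <- data.frame(
    is_target = events$option_id == events$cued_target,
    artifact = flag_artifact_events(events, syn$artifact_onsets, fs,
                                    params, n_t)
  )
  rec <- recording(
    syn$signals, mont, events,
    metadata = list(kind = "synthetic", condition = "calibration",
                    seed = seed)
  )
  structure(
    list(recording = rec,
         ground_truth = list(events = gt,
                             artifact_onsets = syn$artifact_onsets,
                             cued_targets = schedule$cued_targets)),
    class = "bmi_sim_session"
  )
}

# Round-based online flashing sequence starting at time 0.
online_flash_events <- function(cued_target, config, sampling_rate,
                                condition_tag) {
  n_flashes <- ceiling(config$attempt_timeout_s / 0.150) + config$n_c
  n_rounds <- ceiling(n_flashes / config$n_c)
  opts <- integer(0)
  last <- NA_integer_
  for (rd in seq_len(n_rounds)) {
    perm <- sample.int(config$n_c) - 1L
    while (!is.na(last) && perm[1] == last) perm <- sample.int(config$n_c) - 1L
    opts <- c(opts, perm)
    last <- perm[config$n_c]
  }
  onset_s <- 0.150 * (seq_along(opts) - 1)
  keep <- onset_s <= config$attempt_timeout_s
  data.frame(
    onset_sample = as.integer(round(onset_s[keep] * sampling_rate)),
    option_id = opts[keep],
    run_id = 0L,
    cued_target = as.integer(cued_target),
    condition_tag = condition_tag,
    stringsAsFactors = FALSE
  )
}

# Classify every event of a run and feed the controller.
score_run <- function(bands, run_events, trained, config) {
  fs <- bands$band_4_40$montage$sampling_rate
  n_t <- epoch_samples(fs, 800)
  n <- ncol(bands$band_4_40$signals)
  first_onset <- run_events$onset_sample[1]
  if (any(run_events$onset_sample + n_t > n)) {
    return(structure(
      list(kind = "invalid", option_id = NA_integer_,
           selection_time_s = NA_real_, n_events = 0L, n_artifacts = 0L),
      class = "bmi_attempt"))
  }
  labels <- character(nrow(run_events))
  for (i in seq_len(nrow(run_events))) {
    epoch <- extract_epoch(bands, run_events[i, ])
    q <- assess_quality(epoch)
    if (q$verdict == "artifact") {
      labels[i] <- "artifact"
    } else {
      feats <- flatten_features(
        apply_filters(downsample_epoch(epoch, quality = q),
                      trained$filter_bank))
      labels[i] <- classify_epochs(feats, trained$model)
    }
  }
  stream <- data.frame(
    time_s = (run_events$onset_sample - first_onset) / fs + n_t / fs,
    option_id = run_events$option_id,
    label = labels,
    stringsAsFactors = FALSE
  )
  run_attempt(stream, config)
}

#' Simulate one online selection attempt end to end
#'
#' Generates a fresh flashing sequence and its synthetic EEG, then runs the
#' complete online chain (band filtering, epoching, validation, decimation,
#' spatial projection, classification, interface controller) until a
#' selection fires or the attempt times out. Label timestamps are the epoch
#' completion times (onset + 800 ms).
#'
#' @param trained A [train_system()] result.
#' @param cued_target Attended option id.
#' @param params See [sim_params()].
#' @param config See [controller_config()].
#' @param seed Integer seed.
#' @param condition_tag Condition recorded in the events.
#' @param keep_recording Attach the synthetic recording to the result (for
#'   replay checks).
#' @return A `bmi_attempt` with `cued_target` attached.
#' @export
simulate_online_attempt <- function(trained, cued_target,
                                    params = sim_params(),
                                    config = controller_config(), seed = 1,
                                    condition_tag = "online_without_orthosis",
                                    keep_recording = FALSE) {
  stopifnot(inherits(trained, "bmi_system"))
  mont <- default_montage()
  fs <- mont$sampling_rate
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(substream_seed(seed, 3L))  # schedule substream
  events <- online_flash_events(cued_target, config, fs, condition_tag)
  n_t <- epoch_samples(fs, 800)
  n_samples <- max(events$onset_sample) + n_t + as.integer(fs)
  syn <- synth_session_signal(n_samples, events, params, mont, seed)
  rec <- recording(syn$signals, mont, events,
                   metadata = list(kind = "synthetic", seed = seed))
  bands <- filter_bands(rec)
  att <- score_run(bands, rec$events, trained, config)
  att$cued_target <- as.integer(cued_target)
  if (keep_recording) att$recording <- rec
  att
}

#' Replay a recorded session through a trained system
#'
#' Deterministically re-executes the full pipeline over the recorded event
#' stream, one attempt per `run_id`, scoring each run against its cued
#' target. Runs whose epochs extend beyond the recorded signal (truncated
#' recordings) are reported as `invalid`; earlier runs are unaffected.
#'
#' @param rec A `bmi_recording` with online events carrying cued targets.
#' @param trained A [train_system()] result.
#' @param config See [controller_config()].
#' @return List of `bmi_attempt`, one per run, each with `cued_target`.
#' @export
replay_session <- function(rec, trained, config = controller_config()) {
  stopifnot(inherits(rec, "bmi_recording"), inherits(trained, "bmi_system"))
  if (!nrow(rec$events)) stop_validation("recording has no events")
  if (anyNA(rec$events$cued_target)) {
    stop_validation("replay requires cued_target on every event")
  }
  bands <- filter_bands(rec)
  runs <- split(rec$events, rec$events$run_id)
  lapply(runs, function(run_events) {
    run_events <- run_events[order(run_events$onset_sample), , drop = FALSE]
    att <- score_run(bands, run_events, trained, config)
    att$cued_target <- run_events$cued_target[1]
    att
  })
}
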