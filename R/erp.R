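#' ERP analysis window specification
#'
#' The ERP analysis uses the broadband (4-40 Hz) signal with 200 ms of
#' pre-stimulus and 800 ms of post-stimulus samples; at 256 Hz that is 51
#' pre- and 204 post-stimulus time points (floor rule).
#'
#' @param pre_ms,post_ms Window lengths in milliseconds.
#' @param sampling_rate Hz.
#' @return Named list with `pre`, `post` sample counts and the inputs.
#' @export
erp_window_spec <- function(pre_ms = 200, post_ms = 800,
                            sampling_rate = 256) {
  list(pre_ms = pre_ms, post_ms = post_ms, sampling_rate = sampling_rate,
       pre = epoch_samples(sampling_rate, pre_ms),
       post = epoch_samples(sampling_rate, post_ms))
}

#' Two-tailed baseline amplitude band from a kernel density estimate
#'
#' Estimates the probability density of the baseline samples with a
#' Gaussian kernel (normal-reference bandwidth, optionally scaled) and
#' returns the `alpha/2` and `1 - alpha/2` quantiles of the estimated
#' distribution. Amplitudes outside this band are deemed significant at
#' level `alpha`, two-tailed. A constant input yields the degenerate band
#' `(c, c)`, flagged via the `degenerate` attribute.
#'
#' @param baseline_samples Numeric vector, at least 10 values.
#' @param alpha Significance level in `(0, 1)`.
#' @param bw_mult Multiplier on the normal-reference bandwidth.
#' @return Numeric `c(lower, upper)` with attribute `degenerate`.
#' @export
baseline_band <- function(baseline_samples, alpha = 0.05, bw_mult = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop_parameter("alpha must lie strictly between 0 and 1")
  }
  x <- baseline_samples[is.finite(baseline_samples)]
  if (length(x) < 10) {
    stop_validation("need at least 10 baseline samples")
  }
  if (stats::sd(x) == 0) {
    out <- c(lower = x[1], upper = x[1])
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  bw <- stats::bw.nrd(x) * bw_mult
  d <- stats::density(x, bw = bw, n = 2048, cut = 4)
  cdf <- cumsum(d$y)
  cdf <- cdf / cdf[length(cdf)]
  lower <- d$x[which(cdf >= alpha / 2)[1]]
  upper <- d$x[which(cdf >= 1 - alpha / 2)[1]]
  out <- c(lower = lower, upper = upper)
  attr(out, "degenerate") <- FALSE
  out
}

#' Extract baseline-plus-post-stimulus ERP epochs from a broadband recording
#'
#' Helper building the matrices [erp_significance()] consumes: for each
#' event, channels x (pre + post) samples of the 4-40 Hz filtered signal
#' around the stimulus onset.
#'
#' @param filtered_4_40 The 4-40 Hz filtered `bmi_recording`.
#' @param events Event rows to epoch (default: all events of the recording).
#' @param spec See [erp_window_spec()].
#' @return List of channels x (pre + post) matrices.
#' @export
extract_erp_epochs <- function(filtered_4_40, events = filtered_4_40$events,
                               spec = erp_window_spec()) {
  n <- ncol(filtered_4_40$signals)
  lapply(seq_len(nrow(events)), function(i) {
    onset <- events$onset_sample[i]
    if (onset - spec$pre < 0 || onset + spec$post > n) {
      stop_validation(sprintf(
        "event row %d: ERP window [%d, %d) outside the recording", i,
        onset - spec$pre, onset + spec$post))
    }
    filtered_4_40$signals[, (onset - spec$pre + 1):(onset + spec$post),
                          drop = FALSE]
  })
}

#' Pointwise ERP significance against the pre-stimulus baseline
#'
#' Averages the epochs of each class per channel, subtracts the mean of the
#' pre-stimulus interval from the whole averaged waveform (baseline
#' correction), estimates the baseline amplitude distribution per channel
#' from the averaged waveform's own 51 pre-stimulus samples by kernel
#' density estimation, and flags every post-stimulus time point whose
#' averaged amplitude falls outside the two-tailed `alpha` band (+1 above,
#' -1 below, 0 inside). Positive and negative flags are mutually exclusive
#' by construction.
#'
#' @param epochs_by_class Named list (e.g. `target`, `nontarget`), each a
#'   list of channels x (pre + post) matrices from [extract_erp_epochs()].
#' @param spec See [erp_window_spec()].
#' @param alpha Two-tailed significance level.
#' @param channel_names Channel labels for the output.
#' @return Object of class `bmi_erp_result`: per class, the baseline-
#'   corrected mean waveform, the per-channel KDE band, and the signed
#'   significance mask over post-stimulus points; plus the time axes.
#' @export
erp_significance <- function(epochs_by_class, spec = erp_window_spec(),
                             alpha = 0.05, channel_names = NULL) {
  n_tot <- spec$pre + spec$post
  classes <- lapply(epochs_by_class, function(eps) {
    if (!length(eps)) stop_validation("empty epoch list for a class")
    ok <- vapply(eps, function(m) is.matrix(m) && ncol(m) == n_tot,
                 logical(1))
    if (!all(ok)) {
      stop_validation(sprintf(
        "epochs must carry %d (= %d pre + %d post) samples",
        n_tot, spec$pre, spec$post))
    }
    avg <- Reduce(`+`, eps) / length(eps)
    # baseline-correct each channel by its pre-stimulus mean
    base_mean <- rowMeans(avg[, seq_len(spec$pre), drop = FALSE])
    avg <- avg - base_mean
    n_e <- nrow(avg)
    band <- matrix(NA_real_, n_e, 2,
                   dimnames = list(NULL, c("lower", "upper")))
    mask <- matrix(0L, n_e, spec$post)
    for (e in seq_len(n_e)) {
      b <- baseline_band(avg[e, seq_len(spec$pre)], alpha)
      band[e, ] <- b
      post <- avg[e, (spec$pre + 1):n_tot]
      mask[e, post > b["upper"]] <- 1L
      mask[e, post < b["lower"]] <- -1L
    }
    list(mean = avg, band = band, mask = mask, n_epochs = length(eps))
  })
  fs <- spec$sampling_rate
  structure(
    list(classes = classes,
         alpha = alpha,
         spec = spec,
         time_ms = (seq_len(n_tot) - spec$pre - 1) * 1000 / fs,
         post_time_ms = (seq_len(spec$post) - 1) * 1000 / fs,
         channel_names = channel_names),
    class = "bmi_erp_result"
  )
}

#' Export an ERP result as TSV
#'
#' One row per channel and post-stimulus time point: class means, the
#' target-class baseline band, and the signed target-class significance
#' flag.
#'
#' @param result A `bmi_erp_result` with classes `target` and `nontarget`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_erp_result <- function(result, path) {
  stopifnot(inherits(result, "bmi_erp_result"))
  tgt <- result$classes$target
  nt <- result$classes$nontarget
  if (is.null(tgt)) stop_validation("result lacks a 'target' class")
  n_e <- nrow(tgt$mean)
  pre <- result$spec$pre
  chan <- result$channel_names
  if (is.null(chan)) chan <- paste0("ch", seq_len(n_e))
  rows <- do.call(rbind, lapply(seq_len(n_e), function(e) {
    data.frame(
      channel = chan[e],
      time_ms = result$post_time_ms,
      mean_target = tgt$mean[e, (pre + 1):ncol(tgt$mean)],
      mean_nontarget = if (is.null(nt)) NA_real_ else
        nt$mean[e, (pre + 1):ncol(nt$mean)],
      lower = unname(tgt$band[e, "lower"]),
      upper = unname(tgt$band[e, "upper"]),
      sig_flag = tgt$mask[e, ]
    )
  }))
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}
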