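#' Calibration-session configuration
#'
#' Geometry of the calibration routine: eight cued runs; per run, 33 rounds
#' in which each of the six options flashes exactly once (balanced
#' randomization), at a 150 ms stimulus cycle (75 ms face icon + 75 ms
#' blank), so each run flashes for `198 x 0.15 = 29.7` s. The non-flashing
#' phases (fixation 3 s, cue 2 s, preparation 2 s, rest 3.3 s) pad each run
#' to 40 s and the session to 320 s. Over the session this yields 264
#' target and 1,320 non-target flash epochs.
#'
#' @param n_runs Number of cued runs.
#' @param rounds_per_run Rounds (balanced 6-flash blocks) per run.
#' @param n_c Number of options.
#' @param cycle_s Flash cycle duration in seconds.
#' @param fixation_s,cue_s,preparation_s,rest_s Non-flashing phase durations.
#' @param balanced_targets Draw the 8 cued targets without replacement as
#'   far as possible (default FALSE: uniform draws).
#' @return Named list.
#' @export
calibration_config <- function(n_runs = 8, rounds_per_run = 33, n_c = 6,
                               cycle_s = 0.150, fixation_s = 3, cue_s = 2,
                               preparation_s = 2, rest_s = 3.3,
                               balanced_targets = FALSE) {
  list(n_runs = n_runs, rounds_per_run = rounds_per_run, n_c = n_c,
       cycle_s = cycle_s, fixation_s = fixation_s, cue_s = cue_s,
       preparation_s = preparation_s, rest_s = rest_s,
       balanced_targets = balanced_targets)
}

run_duration_s <- function(config) {
  config$fixation_s + config$cue_s + config$preparation_s +
    config$rounds_per_run * config$n_c * config$cycle_s + config$rest_s
}

#' Build a calibration schedule
#'
#' Draws, reproducibly under `seed`, the cued target of every run and a
#' uniformly random permutation of the options for every round. Round
#' permutations are redrawn when they would make an option flash twice in a
#' row across a round boundary.
#'
#' @param seed Integer seed.
#' @param config See [calibration_config()].
#' @param sampling_rate Sampling rate used to place onset samples.
#' @return Object of class `bmi_schedule`: the event table (calibration
#'   condition, cued targets filled in), per-run cued targets, phase
#'   timings, and the total session duration.
#' @export
build_schedule <- function(seed, config = calibration_config(),
                           sampling_rate = 256) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(substream_seed(seed, 1L))

  n_c <- config$n_c
  cued <- if (config$balanced_targets) {
    sample(rep_len(seq_len(n_c) - 1L, config$n_runs))
  } else {
    sample.int(n_c, config$n_runs, replace = TRUE) - 1L
  }
  run_dur <- run_duration_s(config)
  flash_offset <- config$fixation_s + config$cue_s + config$preparation_s

  rows <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    opts <- integer(0)
    last <- NA_integer_
    for (rd in seq_len(config$rounds_per_run)) {
      perm <- sample.int(n_c) - 1L
      while (!is.na(last) && perm[1] == last) {
        perm <- sample.int(n_c) - 1L
      }
      opts <- c(opts, perm)
      last <- perm[n_c]
    }
    onset_s <- (r - 1) * run_dur + flash_offset +
      config$cycle_s * (seq_along(opts) - 1)
    rows[[r]] <- data.frame(
      onset_sample = as.integer(round(onset_s * sampling_rate)),
      option_id = opts,
      run_id = r - 1L,
      cued_target = cued[r],
      condition_tag = "calibration",
      stringsAsFactors = FALSE
    )
  }
  events <- do.call(rbind, rows)
  structure(
    list(events = events,
         cued_targets = cued,
         config = config,
         sampling_rate = sampling_rate,
         run_duration_s = run_dur,
         total_duration_s = config$n_runs * run_dur,
         seed = seed),
    class = "bmi_schedule"
  )
}

substream_seed <- function(seed, k) {
  # named substreams derived from one session seed; keep within 32-bit range
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

#' Pre-process a calibration recording into labeled training epochs
#'
#' Filters the recording into the three system bands, extracts the 800 ms
#' epoch of every calibration flash, validates it, and decimates the valid
#' ones. An epoch is labeled `target` when the flashed option equals the
#' run's cued target.
#'
#' @param rec A calibration `bmi_recording` whose events carry `cued_target`.
#' @param filter_order FIR order.
#' @param min_target Minimum number of valid target epochs required.
#' @return List of class `bmi_training_set`: `target` and `nontarget` lists
#'   of `bmi_depoch`, `artifact_count`, `counts`, and the per-event verdicts.
#' @export
assemble_training_set <- function(rec, filter_order = 256, min_target = 20) {
  ev <- rec$events[rec$events$condition_tag == "calibration", , drop = FALSE]
  if (!nrow(ev)) stop_validation("recording has no calibration events")
  if (anyNA(ev$cued_target)) {
    stop_validation("calibration events must carry cued_target")
  }
  bands <- filter_bands(rec, order = filter_order)
  target <- list(); nontarget <- list()
  artifact_count <- 0L
  verdicts <- character(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    epoch <- extract_epoch(bands, ev[i, ])
    q <- assess_quality(epoch)
    if (q$verdict == "artifact") {
      artifact_count <- artifact_count + 1L
      verdicts[i] <- "artifact"
      next
    }
    dep <- downsample_epoch(epoch, quality = q)
    if (ev$option_id[i] == ev$cued_target[i]) {
      target[[length(target) + 1L]] <- dep
      verdicts[i] <- "target"
    } else {
      nontarget[[length(nontarget) + 1L]] <- dep
      verdicts[i] <- "non-target"
    }
  }
  if (length(target) < min_target) {
    stop_estimation(sprintf(
      "only %d valid target epochs (need >= %d) to train",
      length(target), min_target))
  }
  structure(
    list(target = target, nontarget = nontarget,
         artifact_count = artifact_count,
         counts = c(target = length(target),
                    nontarget = length(nontarget),
                    artifact = artifact_count),
         verdicts = verdicts),
    class = "bmi_training_set"
  )
}

#' Train the full system from a calibration recording
#'
#' Runs the calibration pipeline end to end: pre-process and label the
#' epochs, fit the CCA spatial filter bank on the valid target epochs,
#' project both classes through the bank, and run stepwise RLDA selection on
#' the flattened projections. Optionally estimates out-of-sample performance
#' with an outer stratified cross-validation in which the whole
#' stepwise-plus-RLDA stage is refit per fold.
#'
#' @param rec Calibration `bmi_recording`.
#' @param n_w Number of spatial filters retained.
#' @param stepwise See [stepwise_config()].
#' @param filter_order FIR order.
#' @param evaluate_cv Run the outer CV (slower); when FALSE the report
#'   carries the selection-time CV accuracies only.
#' @param cv_seed Fold seed of the outer CV.
#' @return Object of class `bmi_system`: `filter_bank`, `model`, `report`
#'   (epoch/artifact counts, CV accuracies, seeds).
#' @export
train_system <- function(rec, n_w = 4, stepwise = stepwise_config(),
                         filter_order = 256, evaluate_cv = FALSE,
                         cv_seed = 1) {
  ts <- assemble_training_set(rec, filter_order)
  bank <- fit_cca_filters(ts$target, n_w = n_w)
  epochs <- c(ts$target, ts$nontarget)
  labels <- c(rep("target", length(ts$target)),
              rep("non-target", length(ts$nontarget)))
  features <- project_epochs(epochs, bank)
  model <- stepwise_select_and_fit(features, labels, stepwise)
  report <- list(counts = ts$counts,
                 artifact_count = ts$artifact_count,
                 selection_cv = model$cv,
                 n_selected = length(model$selected),
                 correlations = bank$correlations)
  if (evaluate_cv) {
    report$cv <- crossval(features, labels, k = stepwise$n_folds,
                          seed = cv_seed, config = stepwise)
  }
  structure(
    list(filter_bank = bank, model = model, report = report,
         n_t_hat = ncol(ts$target[[1]]$Y)),
    class = "bmi_system"
  )
}

#' @export
print.bmi_system <- function(x, ...) {
  cat("<bmi_system>\n")
  cat(sprintf("  epochs: %d target / %d non-target / %d artifact\n",
              x$report$counts["target"], x$report$counts["nontarget"],
              x$report$counts["artifact"]))
  cat(sprintf("  spatial filters: %d (correlations %s)\n",
              x$filter_bank$n_w,
              paste(sprintf("%.3f", x$filter_bank$correlations),
                    collapse = ", ")))
  cat(sprintf("  features selected: %d; selection CV weighted acc %.1f%%\n",
              length(x$model$selected), x$report$selection_cv$acc_weighted))
  invisible(x)
}
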