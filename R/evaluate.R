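#' Stratified k-fold cross-validation of the classification stage
#'
#' Refits the full stepwise-selection-plus-RLDA stage inside every training
#' fold and pools the held-out predictions; reports per-class accuracies and
#' the weighted accuracy `acc_w = 0.5 (acc_target + acc_nontarget)` in
#' percent. Folds are stratified so both classes appear in every fold.
#'
#' @param features Observations x candidate-features matrix.
#' @param labels Class labels (`"target"`/`"non-target"` or logical).
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @param config Stepwise configuration used inside each fold.
#' @param fit_fun Model-fitting function `(X, labels) -> bmi_rlda`; defaults
#'   to stepwise selection with `config`.
#' @return Object of class `bmi_cv_report`: `acc_target`, `acc_nontarget`,
#'   `acc_weighted` (percent), per-fold breakdown, `n_folds`, `seed`.
#' @export
crossval <- function(features, labels, k = 5, seed = 1,
                     config = stepwise_config(),
                     fit_fun = function(X, y) stepwise_select_and_fit(X, y, config)) {
  features <- as.matrix(features)
  is_target <- as_target_logical(labels)
  fold <- stratified_folds(is_target, k, seed)
  hits_t <- 0; tot_t <- 0; hits_nt <- 0; tot_nt <- 0
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- fit_fun(features[tr, , drop = FALSE], is_target[tr])
    pred <- classify_epochs(features[!tr, , drop = FALSE], model) == "target"
    y <- is_target[!tr]
    ft <- sum(pred & y); fnt <- sum(!pred & !y)
    hits_t <- hits_t + ft; tot_t <- tot_t + sum(y)
    hits_nt <- hits_nt + fnt; tot_nt <- tot_nt + sum(!y)
    per_fold[[f]] <- c(acc_target = 100 * ft / sum(y),
                       acc_nontarget = 100 * fnt / sum(!y))
  }
  acc_t <- 100 * hits_t / tot_t
  acc_nt <- 100 * hits_nt / tot_nt
  structure(
    list(acc_target = acc_t, acc_nontarget = acc_nt,
         acc_weighted = 0.5 * (acc_t + acc_nt),
         per_fold = do.call(rbind, per_fold),
         n_folds = k, seed = seed),
    class = "bmi_cv_report"
  )
}

#' Permutation test of the cross-validated weighted accuracy
#'
#' Under the null hypothesis that class labels are exchangeable, re-runs the
#' cross-validated pipeline on `m` random label permutations and reports the
#' smoothed p-value `(1 + #{permuted >= observed}) / (1 + m)`, which is
#' always positive.
#'
#' @inheritParams crossval
#' @param m Number of permutations (>= 1; the study default is 10,000).
#' @return Object of class `bmi_permutation_report`: `observed` (weighted
#'   accuracy, percent), `m`, `p_value`, the permuted accuracies.
#' @export
permutation_test <- function(features, labels, m = 1000, seed = 1, k = 5,
                             config = stepwise_config(),
                             fit_fun = function(X, y)
                               stepwise_select_and_fit(X, y, config)) {
  if (!is.numeric(m) || m < 1) stop_parameter("m must be at least 1")
  is_target <- as_target_logical(labels)
  observed <- crossval(features, is_target, k = k, seed = seed,
                       config = config, fit_fun = fit_fun)$acc_weighted
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(substream_seed(seed, 2L))
  permuted <- numeric(m)
  for (i in seq_len(m)) {
    y_perm <- sample(is_target)
    permuted[i] <- tryCatch(
      crossval(features, y_perm, k = k, seed = seed, config = config,
               fit_fun = fit_fun)$acc_weighted,
      bmi_error = function(e) 50)  # no informative features = chance
  }
  structure(
    list(observed = observed, m = m,
         p_value = (1 + sum(permuted >= observed)) / (1 + m),
         permuted = permuted),
    class = "bmi_permutation_report"
  )
}

#' Wolpaw information transfer rate
#'
#' Bits per selection
#' `B = log2(n_c) + acc log2(acc) + (1 - acc) log2((1 - acc) / (n_c - 1))`
#' with the conventions `0 log2 0 = 0` at both accuracy boundaries, and the
#' transfer rate `ITR = 60 B / t_avg` in bit/min.
#'
#' @param acc Selection accuracy as a fraction in `[0, 1]`.
#' @param n_c Number of selectable options (>= 2).
#' @param t_avg Average selection time in seconds, or NA (then only `B` is
#'   returned).
#' @return List with `B` (bits/selection) and `itr` (bit/min, NA when
#'   `t_avg` is NA).
#' @export
itr <- function(acc, n_c = 6, t_avg = NA_real_) {
  if (!is.numeric(acc) || acc < 0 || acc > 1) {
    stop_parameter("acc must lie in [0, 1]")
  }
  if (n_c < 2) stop_parameter("n_c must be at least 2")
  if (!is.na(t_avg) && t_avg <= 0) {
    stop_parameter("t_avg must be positive")
  }
  B <- log2(n_c) +
    (if (acc > 0) acc * log2(acc) else 0) +
    (if (acc < 1) (1 - acc) * log2((1 - acc) / (n_c - 1)) else 0)
  list(B = B, itr = if (is.na(t_avg)) NA_real_ else 60 * B / t_avg)
}

#' Summarize online selection attempts
#'
#' Counts an attempt as correct when the selected option equals the cued
#' target; timeouts and wrong selections are failures. The average selection
#' time `t_avg` is taken over the correct selections (timeouts have no
#' selection time). `B` and the ITR follow [itr()].
#'
#' @param attempts List of `bmi_attempt` objects (or lists with `kind`,
#'   `option_id`, `selection_time_s`).
#' @param cued_targets Integer vector of cued options, one per attempt.
#' @param n_c Number of options.
#' @param condition_tag Optional condition label carried into the report.
#' @return Object of class `bmi_online_report`: `n_att`, `n_sel`,
#'   `acc_online` (percent), `t_avg` (s), `B`, `itr` (bit/min), `n_c`.
#' @export
online_report <- function(attempts, cued_targets, n_c = 6,
                          condition_tag = NA_character_) {
  if (!length(attempts)) stop_validation("no attempts to report")
  if (length(cued_targets) != length(attempts)) {
    stop_validation("cued_targets must match attempts in length")
  }
  selected <- vapply(attempts, function(a)
    if (identical(a$kind, "select")) as.integer(a$option_id) else
      NA_integer_, integer(1))
  times <- vapply(attempts, function(a)
    as.numeric(a$selection_time_s %||% NA_real_), numeric(1))
  correct <- !is.na(selected) & selected == cued_targets
  n_att <- length(attempts)
  n_sel <- sum(correct)
  acc <- n_sel / n_att
  t_avg <- if (n_sel > 0) mean(times[correct]) else NA_real_
  rate <- itr(acc, n_c, t_avg)
  structure(
    list(n_att = n_att, n_sel = n_sel, acc_online = 100 * acc,
         t_avg = t_avg, B = rate$B, itr = rate$itr, n_c = n_c,
         condition_tag = condition_tag),
    class = "bmi_online_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare paired performance metrics between two conditions
#'
#' Two-sided tests between condition vectors (e.g. selection times without
#' vs with the orthosis): a paired t-test (`t`, `df = n - 1`, `p`) or the
#' Wilcoxon rank sum test for unpaired group comparisons.
#'
#' @param values_a,values_b Numeric vectors; for `paired_t` of equal length
#'   with pairwise correspondence, pairs with any NA are dropped.
#' @param method `"paired_t"` or `"ranksum"`.
#' @return List with `statistic`, `df` (paired t only), `p_value`, `n`,
#'   `method`.
#' @export
compare_conditions <- function(values_a, values_b,
                               method = c("paired_t", "ranksum")) {
  method <- match.arg(method)
  if (method == "paired_t") {
    if (length(values_a) != length(values_b)) {
      stop_validation("paired_t requires equal-length vectors")
    }
    keep <- stats::complete.cases(values_a, values_b)
    a <- values_a[keep]; b <- values_b[keep]
    if (length(a) < 3) stop_validation("need at least 3 complete pairs")
    if (stats::sd(a - b) == 0) {
      # identical pairs: no evidence of a difference
      return(list(statistic = 0, df = length(a) - 1, p_value = 1,
                  n = length(a), method = method))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, n = length(a), method = method)
  } else {
    a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
    if (length(a) < 3 || length(b) < 3) {
      stop_validation("need at least 3 values per group")
    }
    wt <- stats::wilcox.test(a, b, exact = FALSE)
    list(statistic = unname(wt$statistic), df = NA_real_,
         p_value = wt$p.value, n = length(a) + length(b), method = method)
  }
}

#' Aggregate online reports into a per-condition table
#'
#' @param reports List of `bmi_online_report`.
#' @return Data frame, one row per report, with the report fields.
#' @export
aggregate_reports <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(condition_tag = r$condition_tag, n_att = r$n_att,
               n_sel = r$n_sel, acc_online = r$acc_online,
               t_avg = r$t_avg, B = r$B, itr = r$itr,
               stringsAsFactors = FALSE)
  }))
}
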