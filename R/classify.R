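# Regularized LDA over stepwise-selected, spatially filtered samples.
#
# All fitting goes through class moments (per-class means, pooled centered
# cross-products) so that stepwise selection can score feature subsets by
# slicing precomputed p x p matrices instead of touching the data matrix.

as_target_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- !labels %in% c("target", "non-target")
    if (any(bad)) stop_validation("labels must be 'target' or 'non-target'")
    return(labels == "target")
  }
  if (is.numeric(labels)) return(labels != 0)
  stop_validation("unsupported label vector")
}

# Per-class moments over all p features: means, pooled centered cross-product
# Sc = sum over classes of t(Xc) %*% Xc, and W2 = t(Xc^2) %*% Xc^2 (for the
# shrinkage-intensity estimate).
class_moments <- function(X, is_target) {
  n1 <- sum(is_target)
  n2 <- sum(!is_target)
  if (n1 == 0 || n2 == 0) {
    stop_estimation("both classes must be present to fit the classifier")
  }
  X1 <- X[is_target, , drop = FALSE]
  X2 <- X[!is_target, , drop = FALSE]
  m1 <- colMeans(X1)
  m2 <- colMeans(X2)
  X1c <- sweep(X1, 2, m1)
  X2c <- sweep(X2, 2, m2)
  Xc <- rbind(X1c, X2c)
  list(m1 = m1, m2 = m2, n1 = n1, n2 = n2,
       Sc = crossprod(Xc), W2 = crossprod(Xc^2))
}

# Ledoit-Wolf-style intensity for shrinkage toward the scaled identity,
# computed from the pooled centered cross-products.
lw_gamma <- function(Sc, W2, n, p) {
  Cml <- Sc / n
  sum_c2 <- sum(Cml^2)
  d2 <- sum_c2 - sum(diag(Cml))^2 / p
  if (d2 <= .Machine$double.eps) return(1)
  b2 <- sum(W2) / n^2 - sum_c2 / n
  min(1, max(0, b2 / d2))
}

rlda_from_moments <- function(mom, idx, gamma = "auto") {
  p <- length(idx)
  m1 <- mom$m1[idx]
  m2 <- mom$m2[idx]
  Sc <- mom$Sc[idx, idx, drop = FALSE]
  n <- mom$n1 + mom$n2
  if (identical(gamma, "auto")) {
    gamma <- lw_gamma(Sc, mom$W2[idx, idx, drop = FALSE], n, p)
  }
  Cp <- Sc / max(n - 2, 1)
  mu <- mean(diag(Cp))
  Cshr <- (1 - gamma) * Cp + diag(gamma * mu, p)
  w <- tryCatch(solve(Cshr, m1 - m2), error = function(e) {
    solve(Cshr + diag(1e-10 * max(mu, 1), p), m1 - m2)
  })
  list(weights = as.numeric(w),
       bias = -sum(w * (m1 + m2) / 2),
       gamma = gamma,
       class_means = list(target = m1, `non-target` = m2),
       pooled_covariance = Cp)
}

#' Fit a regularized linear discriminant (RLDA)
#'
#' Two-class LDA whose pooled covariance is shrunk toward the scaled
#' identity, `C(gamma) = (1 - gamma) C + gamma mean(diag(C)) I`. With
#' `gamma = 0` this is classical LDA; with `gamma = 1` the discriminant
#' direction is proportional to the difference of class means. The decision
#' rule uses equal class priors, so the boundary sits midway between the
#' class means regardless of the (heavily unbalanced) class sizes: an epoch
#' is labeled `target` when its affine score is `>= 0`.
#'
#' @param X Numeric matrix, observations x features.
#' @param labels Class labels (`"target"`/`"non-target"`, logical, or 0/1).
#' @param gamma Shrinkage in `[0, 1]`, or `"auto"` for an analytic
#'   Ledoit-Wolf-style estimate recomputed from the training data.
#' @param selected Feature ids the model operates on (default: all columns).
#' @return Object of class `bmi_rlda` with elements `selected`, `weights`,
#'   `bias`, `gamma`, `class_means`, `pooled_covariance`, `labels`.
#' @export
fit_rlda <- function(X, labels, gamma = "auto", selected = seq_len(ncol(X))) {
  X <- as.matrix(X)
  is_target <- as_target_logical(labels)
  if (length(is_target) != nrow(X)) {
    stop_shape("labels length must equal nrow(X)")
  }
  if (!identical(gamma, "auto") &&
      (!is.numeric(gamma) || gamma < 0 || gamma > 1)) {
    stop_parameter("gamma must be in [0, 1] or 'auto'")
  }
  mom <- class_moments(X[, selected, drop = FALSE], is_target)
  fit <- rlda_from_moments(
    list(m1 = mom$m1, m2 = mom$m2, n1 = mom$n1, n2 = mom$n2,
         Sc = mom$Sc, W2 = mom$W2),
    seq_along(selected), gamma)
  structure(
    c(list(selected = as.integer(selected),
           n_features_total = ncol(X),
           labels = c("target", "non-target")),
      fit),
    class = "bmi_rlda"
  )
}

#' Score and classify epochs
#'
#' `rlda_scores()` returns the affine discriminant score of each epoch over
#' the model's selected features; `classify_epochs()` thresholds the scores
#' at zero (`>= 0` is `target`).
#'
#' @param features Numeric vector (one epoch's full feature grid) or matrix
#'   (epochs x features). Must cover the model's selected feature ids.
#' @param model A `bmi_rlda`.
#' @return Scores (numeric) or labels (character vector).
#' @export
rlda_scores <- function(features, model) {
  stopifnot(inherits(model, "bmi_rlda"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) < max(model$selected)) {
    stop_shape(sprintf(
      "feature matrix has %d columns but the model needs feature id %d",
      ncol(features), max(model$selected)))
  }
  as.numeric(features[, model$selected, drop = FALSE] %*% model$weights +
               model$bias)
}

#' @rdname rlda_scores
#' @export
classify_epochs <- function(features, model) {
  ifelse(rlda_scores(features, model) >= 0, "target", "non-target")
}

#' Stepwise configuration
#'
#' Controls the forward-backward feature selection: the scoring criterion is
#' 5-fold cross-validated weighted accuracy `0.5 (acc_target +
#' acc_nontarget)` with improvement threshold `eps`, a cap on the selected
#' set size, and a fixed internal fold seed so selection is deterministic.
#'
#' @param n_folds CV folds used by the scoring criterion.
#' @param eps Minimum score improvement for a forward step; a backward step
#'   may lose at most `eps`.
#' @param max_features Cap on the number of selected features.
#' @param gamma RLDA shrinkage (`"auto"` or fixed value in `[0, 1]`).
#' @param seed Internal fold-assignment seed.
#' @return Named list.
#' @export
stepwise_config <- function(n_folds = 5, eps = 0.001, max_features = 60,
                            gamma = "auto", seed = 17) {
  list(n_folds = n_folds, eps = eps, max_features = max_features,
       gamma = gamma, seed = seed)
}

stratified_folds <- function(is_target, k, seed) {
  if (min(sum(is_target), sum(!is_target)) < k) {
    stop_validation(sprintf(
      "each class needs at least %d observations for %d-fold CV", k, k))
  }
  fold <- integer(length(is_target))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  for (cls in c(TRUE, FALSE)) {
    idx <- which(is_target == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Precompute per-fold training moments and held-out slices once; scoring a
# feature subset then only slices p x p matrices.
fold_machinery <- function(X, is_target, k, seed) {
  fold <- stratified_folds(is_target, k, seed)
  lapply(seq_len(k), function(f) {
    tr <- fold != f
    list(mom = class_moments(X[tr, , drop = FALSE], is_target[tr]),
         X_test = X[!tr, , drop = FALSE],
         y_test = is_target[!tr])
  })
}

# Pooled cross-validated class accuracies of the RLDA over feature set S.
cv_score_subset <- function(folds, S, gamma) {
  hits_t <- 0; tot_t <- 0; hits_nt <- 0; tot_nt <- 0
  for (f in folds) {
    fit <- rlda_from_moments(f$mom, S, gamma)
    sc <- f$X_test[, S, drop = FALSE] %*% fit$weights + fit$bias
    pred_t <- sc >= 0
    hits_t <- hits_t + sum(pred_t & f$y_test)
    tot_t <- tot_t + sum(f$y_test)
    hits_nt <- hits_nt + sum(!pred_t & !f$y_test)
    tot_nt <- tot_nt + sum(!f$y_test)
  }
  acc_t <- hits_t / tot_t
  acc_nt <- hits_nt / tot_nt
  c(weighted = 0.5 * (acc_t + acc_nt), target = acc_t, nontarget = acc_nt)
}

#' Forward-backward stepwise feature selection with RLDA
#'
#' Starts from the empty model (chance weighted accuracy 0.5) and
#' alternates: a forward step adds the candidate feature that maximizes the
#' cross-validated weighted accuracy, provided it improves the current score
#' by more than `eps`; a backward step removes an included feature whose
#' removal does not reduce the score by more than `eps` (taking the removal
#' that leaves the highest score). Selection stops when neither step changes
#' the feature set. Ties in either step are broken toward the lowest feature
#' id. The returned model is refit on all observations over the final set.
#'
#' @param X Feature matrix, observations x candidates (filter-major flattened
#'   projections; see [flatten_features()]).
#' @param labels Class labels.
#' @param config See [stepwise_config()].
#' @return A `bmi_rlda` with extra elements `cv` (selection-time CV
#'   accuracies) and `n_steps`.
#' @export
stepwise_select_and_fit <- function(X, labels, config = stepwise_config()) {
  X <- as.matrix(X)
  is_target <- as_target_logical(labels)
  n_min <- min(sum(is_target), sum(!is_target))
  if (n_min < config$n_folds) {
    stop_validation(sprintf("need at least %d observations per class",
                            config$n_folds))
  }
  if (n_min < 20) {
    warning(sprintf("only %d observations in the smaller class; ", n_min),
            "selection may be unstable")
  }
  p <- ncol(X)
  folds <- fold_machinery(X, is_target, config$n_folds, config$seed)

  S <- integer(0)
  score <- 0.5
  max_iter <- 2L * config$max_features
  n_steps <- 0L
  repeat {
    changed <- FALSE
    # forward
    if (length(S) < config$max_features) {
      candidates <- setdiff(seq_len(p), S)
      best_s <- -Inf; best_j <- NA_integer_
      for (j in candidates) {
        s <- cv_score_subset(folds, c(S, j), config$gamma)[["weighted"]]
        if (s > best_s + 1e-15) { best_s <- s; best_j <- j }
      }
      if (!is.na(best_j) && best_s > score + config$eps) {
        S <- c(S, best_j)
        score <- best_s
        changed <- TRUE
      }
    }
    # backward (never drop to the empty model)
    if (length(S) >= 2) {
      best_s <- -Inf; best_j <- NA_integer_
      for (j in sort(S)) {
        s <- cv_score_subset(folds, setdiff(S, j), config$gamma)[["weighted"]]
        if (s > best_s + 1e-15) { best_s <- s; best_j <- j }
      }
      if (!is.na(best_j) && best_s >= score - config$eps) {
        S <- setdiff(S, best_j)
        score <- best_s
        changed <- TRUE
      }
    }
    n_steps <- n_steps + 1L
    if (!changed || n_steps >= max_iter) break
  }

  if (!length(S)) {
    stop_estimation("no informative features: nothing improves on the empty model")
  }
  cv <- cv_score_subset(folds, S, config$gamma)
  model <- fit_rlda(X, is_target, gamma = config$gamma, selected = S)
  model$cv <- list(acc_weighted = 100 * cv[["weighted"]],
                   acc_target = 100 * cv[["target"]],
                   acc_nontarget = 100 * cv[["nontarget"]],
                   n_folds = config$n_folds, seed = config$seed)
  model$n_steps <- n_steps
  model
}

#' Serialize / deserialize a classifier as JSON
#'
#' @param model A `bmi_rlda`.
#' @param path JSON path.
#' @return `read_classifier()` returns a `bmi_rlda`.
#' @export
write_classifier <- function(model, path) {
  jsonlite::write_json(
    list(selected = model$selected, weights = model$weights,
         bias = model$bias, gamma = model$gamma,
         n_features_total = model$n_features_total,
         class_means = model$class_means, cv = model$cv),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(selected = as.integer(obj$selected),
         weights = as.numeric(obj$weights),
         bias = as.numeric(obj$bias),
         gamma = as.numeric(obj$gamma),
         n_features_total = as.integer(obj$n_features_total),
         class_means = obj$class_means,
         labels = c("target", "non-target"),
         cv = obj$cv),
    class = "bmi_rlda"
  )
}
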