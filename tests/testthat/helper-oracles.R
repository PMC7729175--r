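# Independent oracles and fixture builders shared across the suite.

# Brute-force CCA: generalized eigenproblem on the covariance blocks.
cca_oracle <- function(U, V) {
  Uc <- scale(U, center = TRUE, scale = FALSE)
  Vc <- scale(V, center = TRUE, scale = FALSE)
  n <- nrow(Uc)
  Cuu <- crossprod(Uc) / (n - 1)
  Cvv <- crossprod(Vc) / (n - 1)
  Cuv <- crossprod(Uc, Vc) / (n - 1)
  M <- solve(Cuu, Cuv) %*% solve(Cvv, t(Cuv))
  ev <- eigen(M)
  sqrt(pmax(Re(ev$values), 0))
}

# From-scratch LDA with the explicit inverse-pooled-covariance formula.
lda_oracle <- function(X, is_target) {
  X1 <- X[is_target, , drop = FALSE]
  X2 <- X[!is_target, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  S <- (crossprod(sweep(X1, 2, m1)) + crossprod(sweep(X2, 2, m2))) /
    (nrow(X) - 2)
  w <- solve(S, m1 - m2)
  list(weights = as.numeric(w), bias = -sum(w * (m1 + m2) / 2))
}

# Build a bmi_epoch directly from matrices (for quality-metric tests).
epoch_from_matrices <- function(X_4_40, X_20_40 = NULL, X_4_14 = NULL) {
  if (is.null(X_20_40)) X_20_40 <- matrix(0, nrow(X_4_40), ncol(X_4_40))
  if (is.null(X_4_14)) X_4_14 <- X_4_40
  structure(
    list(X_4_14 = X_4_14, X_20_40 = X_20_40, X_4_40 = X_4_40,
         event = list(onset_sample = 0L, option_id = 0L),
         n_t = ncol(X_4_40)),
    class = "bmi_epoch"
  )
}

# List of random downsampled-epoch matrices.
random_epoch_set <- function(n, n_e = 8, n_t = 51, sd = 1) {
  lapply(seq_len(n), function(i) matrix(rnorm(n_e * n_t, sd = sd), n_e, n_t))
}

# Two-class feature fixture: one informative column among noise.
planted_features <- function(n_per_class = 60, p = 21, informative = 7,
                             separation = 3, seed = 99) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  labels <- rep(c("target", "non-target"), each = n_per_class)
  X[labels == "target", informative] <-
    X[labels == "target", informative] + separation
  list(X = X, labels = labels, informative = informative)
}

# Small synthetic calibration session (reduced geometry, same generator).
small_calibration <- function(seed = 1, amp = 5, n_runs = 4,
                              rounds = 15, artifact_rate = 2) {
  sch <- build_schedule(seed, calibration_config(n_runs = n_runs,
                                                 rounds_per_run = rounds))
  simulate_calibration(
    sch, sim_params(erp_amplitude = amp,
                    artifact_rate_per_min = artifact_rate), seed = seed)
}

expect_bmi_error <- function(expr, class) {
  expect_error(expr, class = class)
}
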