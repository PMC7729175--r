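#' Average ERP waveform of a set of epochs
#'
#' Entrywise arithmetic mean over a set of downsampled, artifact-free
#' target-class epochs.
#'
#' @param epochs List of `bmi_depoch` objects (or bare channels-by-time
#'   matrices) sharing one shape.
#' @return Channels-by-time matrix of class means.
#' @export
average_erp <- function(epochs) {
  mats <- depoch_matrices(epochs)
  Reduce(`+`, mats) / length(mats)
}

depoch_matrices <- function(epochs) {
  if (!length(epochs)) stop_validation("epoch set is empty")
  mats <- lapply(epochs, function(ep) {
    if (inherits(ep, "bmi_depoch")) ep$Y else ep
  })
  d <- dim(mats[[1]])
  ok <- vapply(mats, function(m) is.matrix(m) && identical(dim(m), d),
               logical(1))
  if (!all(ok)) stop_validation("epochs do not share a common shape")
  mats
}

# Inverse square root of a symmetric PSD matrix, dropping near-null
# directions (relative eigenvalue tolerance `tol`).
inv_sqrt_psd <- function(S, tol = 1e-12) {
  eg <- eigen(S, symmetric = TRUE)
  keep <- eg$values > tol * max(eg$values, 0)
  if (!any(keep)) return(NULL)
  V <- eg$vectors[, keep, drop = FALSE]
  V %*% (t(V) / sqrt(eg$values[keep]))
}

#' Fit CCA spatial filters from target-class epochs
#'
#' Builds the stacked matrices `U` (all transposed target epochs) and `V`
#' (the transposed average ERP repeated once per epoch), both of dimension
#' `(n_t_hat * n_target) x n_e`, and finds the electrode-weight vectors `w`
#' maximizing the canonical correlation between `Uw` and the matching
#' projection of `V`. The `n_w` filters with the highest canonical
#' correlations are retained.
#'
#' Numerically the fit is a whitened cross-covariance SVD: both blocks are
#' column-centered, their covariances ridged by `ridge * mean(diag)` for
#' stability, and the singular vectors back-transformed. Each retained
#' weight vector is normalized to unit Euclidean norm with its
#' largest-magnitude element positive, which fixes the scale/sign left free
#' by the correlation objective; ties among equal correlations keep the
#' lower filter index first.
#'
#' @param epochs List of `bmi_depoch` (target class, artifact-free), length
#'   at least 2. A warning is issued when fewer epochs than channels are
#'   supplied.
#' @param n_w Number of filters to retain, `1 <= n_w <= n_e`.
#' @param ridge Relative ridge added to the covariance diagonals.
#' @return Object of class `bmi_filter_bank`: `W` (`n_e x n_w`),
#'   `correlations` (non-increasing, in `[0,1]`), `n_w`, `n_e`.
#' @export
fit_cca_filters <- function(epochs, n_w = 4, ridge = 1e-8) {
  mats <- depoch_matrices(epochs)
  n_target <- length(mats)
  n_e <- nrow(mats[[1]])
  if (n_target < 2) stop_validation("need at least 2 target epochs")
  if (n_w < 1 || n_w > n_e) {
    stop_parameter(sprintf("n_w must lie in [1, %d]", n_e))
  }
  if (n_target < n_e) {
    warning(sprintf(
      "only %d target epochs for %d channels; filters may be unstable",
      n_target, n_e))
  }
  Ybar <- Reduce(`+`, mats) / n_target
  U <- do.call(rbind, lapply(mats, t))
  V <- do.call(rbind, rep(list(t(Ybar)), n_target))

  Uc <- scale(U, center = TRUE, scale = FALSE)
  Vc <- scale(V, center = TRUE, scale = FALSE)
  n <- nrow(Uc)
  Cuu <- crossprod(Uc) / (n - 1)
  Cvv <- crossprod(Vc) / (n - 1)
  Cuv <- crossprod(Uc, Vc) / (n - 1)
  Cuu <- Cuu + diag(ridge * mean(diag(Cuu)) + 1e-300, n_e)
  Cvv <- Cvv + diag(ridge * mean(diag(Cvv)) + 1e-300, n_e)

  Wu <- inv_sqrt_psd(Cuu)
  Wv <- inv_sqrt_psd(Cvv)
  if (is.null(Wu) || is.null(Wv)) {
    stop_estimation("rank-deficient epoch set: no usable spatial directions")
  }
  K <- Wu %*% Cuv %*% Wv
  sv <- svd(K)
  correlations <- pmin(pmax(sv$d, 0), 1)
  if (max(correlations) < 1e-10) {
    stop_estimation("rank-deficient epoch set: no usable spatial directions")
  }
  W_full <- Wu %*% sv$u
  keep <- seq_len(n_w)
  W <- W_full[, keep, drop = FALSE]
  for (j in seq_len(ncol(W))) {
    w <- W[, j]
    nrm <- sqrt(sum(w^2))
    if (nrm > 0) w <- w / nrm
    if (w[which.max(abs(w))] < 0) w <- -w
    W[, j] <- w
  }
  rownames(W) <- rownames(mats[[1]])
  structure(
    list(W = W, correlations = correlations[keep], n_w = n_w, n_e = n_e,
         all_correlations = correlations),
    class = "bmi_filter_bank"
  )
}

#' Apply a spatial filter bank to an epoch
#'
#' Projects a downsampled epoch onto the retained spatial filters: output
#' row `j` is `t(W[, j]) %*% Y`, giving an `n_w x n_t_hat` virtual-channel
#' matrix.
#'
#' @param epoch A `bmi_depoch` or bare channels-by-time matrix.
#' @param bank A `bmi_filter_bank`.
#' @return Matrix `n_w x n_t_hat`.
#' @export
apply_filters <- function(epoch, bank) {
  stopifnot(inherits(bank, "bmi_filter_bank"))
  Y <- if (inherits(epoch, "bmi_depoch")) epoch$Y else epoch
  if (!is.matrix(Y) || nrow(Y) != bank$n_e) {
    stop_shape(sprintf("epoch has %d channels but bank expects %d",
                       if (is.matrix(Y)) nrow(Y) else -1L, bank$n_e))
  }
  crossprod(bank$W, Y)
}

#' Flatten a projected epoch into the classifier feature vector
#'
#' Feature ordering is filter-major: features `1..n_t_hat` are the first
#' virtual channel's time course, then the second, and so on. Feature id
#' `(j - 1) * n_t_hat + k` (1-based) is virtual channel `j` at time index
#' `k`.
#'
#' @param projected Matrix `n_w x n_t_hat` from [apply_filters()].
#' @return Numeric vector of length `n_w * n_t_hat`.
#' @export
flatten_features <- function(projected) {
  as.vector(t(projected))
}

#' Project a list of epochs into a feature matrix
#'
#' @param epochs List of `bmi_depoch`.
#' @param bank A `bmi_filter_bank`.
#' @return Matrix `n_epochs x (n_w * n_t_hat)`.
#' @export
project_epochs <- function(epochs, bank) {
  t(vapply(epochs, function(ep) flatten_features(apply_filters(ep, bank)),
           numeric(bank$n_w * ncol(if (inherits(epochs[[1]], "bmi_depoch"))
             epochs[[1]]$Y else epochs[[1]]))))
}

#' Serialize / deserialize a filter bank as JSON
#'
#' @param bank A `bmi_filter_bank`.
#' @param path Output (input) JSON path.
#' @param montage Montage whose channel list is hashed into the file.
#' @return `read_filter_bank()` returns a `bmi_filter_bank`.
#' @export
write_filter_bank <- function(bank, path, montage = default_montage()) {
  jsonlite::write_json(
    list(
      weights = unname(bank$W),  # n_e x n_w, serialized row-major
      correlations = bank$correlations,
      all_correlations = bank$all_correlations,
      n_w = bank$n_w,
      n_e = bank$n_e,
      montage_hash = montage_hash(montage)
    ),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_bank
#' @export
read_filter_bank <- function(path, montage = default_montage()) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$montage_hash) &&
      !identical(obj$montage_hash, montage_hash(montage))) {
    stop_validation("filter bank was fitted on a different montage")
  }
  W <- as.matrix(obj$weights)
  storage.mode(W) <- "double"
  rownames(W) <- montage$channel_names
  colnames(W) <- NULL
  structure(
    list(W = W, correlations = as.numeric(obj$correlations),
         n_w = as.integer(obj$n_w), n_e = as.integer(obj$n_e),
         all_correlations = as.numeric(obj$all_correlations)),
    class = "bmi_filter_bank"
  )
}

montage_hash <- function(montage) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(c(montage$channel_names, montage$reference,
                     montage$ground, montage$sampling_rate),
                   collapse = "|"), f)
  unname(tools::md5sum(f))
}
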