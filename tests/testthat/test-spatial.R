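test_that("average ERP is the entrywise mean", {
  set.seed(2)
  single <- random_epoch_set(1)
  expect_equal(average_erp(single), single[[1]])

  M <- matrix(rnorm(8 * 51), 8, 51)
  expect_true(all(average_erp(list(M, -M)) == 0))

  eps <- random_epoch_set(10)
  # brute-force loop oracle
  oracle <- matrix(0, 8, 51)
  for (e in 1:8) for (t in 1:51) {
    oracle[e, t] <- mean(vapply(eps, function(m) m[e, t], numeric(1)))
  }
  expect_lt(max(abs(average_erp(eps) - oracle)), 1e-12)

  expect_bmi_error(average_erp(list(M, matrix(0, 8, 50))),
                   "bmi_validation_error")
})

test_that("identical epochs give a canonical correlation of 1", {
  set.seed(4)
  eps <- rep(list(matrix(rnorm(8 * 51), 8, 51)), 10)
  bank <- fit_cca_filters(eps, n_w = 1)
  # the stabilizing covariance ridge perturbs the exact unit correlation
  # by its own magnitude (1e-8)
  expect_lt(abs(bank$correlations[1] - 1), 1e-7)
})

test_that("the leading filter localizes a channel-specific waveform", {
  set.seed(8)
  n_t <- 51
  waveform <- sin(2 * pi * (1:n_t) / n_t)
  sigma_noise <- 0.2 * sqrt(mean(waveform^2))
  eps <- lapply(1:40, function(i) {
    m <- matrix(rnorm(8 * n_t, sd = sigma_noise), 8, n_t)
    m[3, ] <- m[3, ] + waveform
    m
  })
  bank <- fit_cca_filters(eps, n_w = 4)
  expect_equal(which.max(abs(bank$W[, 1])), 3L)
})

test_that("canonical correlations match brute-force oracles on small instances", {
  set.seed(123)
  for (r in 1:20) {
    eps <- random_epoch_set(12, n_e = 4, n_t = 10)
    bank <- fit_cca_filters(eps, n_w = 4)
    Ybar <- Reduce(`+`, eps) / length(eps)
    U <- do.call(rbind, lapply(eps, t))
    V <- do.call(rbind, rep(list(t(Ybar)), length(eps)))
    expect_lt(max(abs(sort(bank$all_correlations, decreasing = TRUE) -
                        sort(cca_oracle(U, V), decreasing = TRUE))), 1e-6)
    # cross-check against the stats implementation as well
    cc <- stats::cancor(scale(U, scale = FALSE), scale(V, scale = FALSE))
    expect_lt(max(abs(bank$all_correlations[seq_along(cc$cor)] - cc$cor)),
              1e-6)
  }
})

test_that("retained correlations are the top ones and weights are normalized", {
  set.seed(9)
  eps <- lapply(1:60, function(i) {
    m <- matrix(rnorm(8 * 51, sd = 0.3), 8, 51)
    m[2, ] <- m[2, ] + cos(2 * pi * (1:51) / 17)
    m
  })
  bank <- fit_cca_filters(eps, n_w = 3)
  expect_equal(bank$correlations, bank$all_correlations[1:3])
  expect_true(all(diff(bank$all_correlations) <= 1e-12))
  expect_true(all(bank$all_correlations >= 0 & bank$all_correlations <= 1))
  for (j in 1:3) {
    expect_lt(abs(sqrt(sum(bank$W[, j]^2)) - 1), 1e-9)
    expect_gt(bank$W[which.max(abs(bank$W[, j])), j], 0)
  }
})

test_that("epoch scaling leaves correlations fixed and scales projections", {
  set.seed(10)
  eps <- lapply(1:30, function(i) {
    m <- matrix(rnorm(8 * 51, sd = 0.5), 8, 51)
    m[4, ] <- m[4, ] + sin(2 * pi * (1:51) / 13)
    m
  })
  b1 <- fit_cca_filters(eps, n_w = 4)
  b2 <- fit_cca_filters(lapply(eps, function(m) 3.7 * m), n_w = 4)
  expect_equal(b1$correlations, b2$correlations, tolerance = 1e-8)
  p1 <- apply_filters(eps[[1]], b1)
  p2 <- apply_filters(3.7 * eps[[1]], b2)
  expect_equal(p2, 3.7 * p1, tolerance = 1e-6)
})

test_that("white-noise epochs give no spuriously strong correlation", {
  worst <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    bank <- fit_cca_filters(random_epoch_set(200), n_w = 1)
    worst <- max(worst, bank$correlations[1])
  }
  expect_lt(worst, 0.5)
})

test_that("filter application is the per-filter dot product", {
  set.seed(12)
  eps <- random_epoch_set(20)
  bank <- fit_cca_filters(eps, n_w = 4)

  Y <- eps[[1]]
  proj <- apply_filters(Y, bank)
  oracle <- matrix(0, 4, 51)
  for (j in 1:4) for (t in 1:51) {
    oracle[j, t] <- sum(bank$W[, j] * Y[, t])
  }
  expect_lt(max(abs(proj - oracle)), 1e-12)

  indicator <- bank
  indicator$W <- matrix(c(0, 1, 0, 0, 0, 0, 0, 0), ncol = 1)
  indicator$n_w <- 1L
  expect_equal(apply_filters(Y, indicator)[1, ], Y[2, ])

  expect_true(all(apply_filters(matrix(0, 8, 51), bank) == 0))
  expect_bmi_error(apply_filters(matrix(0, 5, 51), bank), "bmi_shape_error")
})

test_that("flattening is filter-major and the bank serializes losslessly", {
  P <- matrix(1:8, nrow = 2, byrow = TRUE)  # 2 filters x 4 time points
  expect_equal(flatten_features(P), as.numeric(1:8))

  set.seed(13)
  bank <- fit_cca_filters(random_epoch_set(20), n_w = 4)
  f <- tempfile(fileext = ".json")
  write_filter_bank(bank, f)
  back <- read_filter_bank(f)
  expect_equal(unname(back$W), unname(bank$W), tolerance = 1e-12)
  expect_equal(back$correlations, bank$correlations, tolerance = 1e-12)
  wrong <- montage(c("C3", "C4"), "ref", "gnd", 512)
  expect_bmi_error(read_filter_bank(f, wrong), "bmi_validation_error")
})

test_that("degenerate epoch sets are rejected", {
  expect_bmi_error(fit_cca_filters(list(matrix(0, 8, 51))),
                   "bmi_validation_error")
  zeroes <- rep(list(matrix(0, 8, 51)), 10)
  expect_bmi_error(fit_cca_filters(zeroes), "bmi_estimation_error")
})
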