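make_sine_recording <- function(freq, amp = 1, secs = 10, n_ch = 8) {
  fs <- 256
  t <- (0:(secs * fs - 1)) / fs
  recording(matrix(rep(amp * sin(2 * pi * freq * t), n_ch),
                   nrow = n_ch, byrow = TRUE))
}

test_that("FIR band-pass has the designed pass/stop behavior", {
  zero <- filter_recording(recording(matrix(0, 8, 2560)), band_spec(4, 14))
  expect_true(all(zero$signals == 0))

  ss <- 1000:1500  # steady state, away from edges
  pass <- filter_recording(make_sine_recording(10), band_spec(4, 14))
  expect_lt(abs(max(abs(pass$signals[1, ss])) - 1), 0.05)

  stopb <- filter_recording(make_sine_recording(50), band_spec(4, 14))
  atten_db <- -20 * log10(max(abs(stopb$signals[1, ss])))
  expect_gt(atten_db, 40)

  expect_bmi_error(
    filter_recording(make_sine_recording(10), band_spec(4, 130)),
    "bmi_parameter_error")
})

test_that("group-delay compensation keeps filtered output stimulus-locked", {
  # a 10 Hz burst starting at sample 1000 must still start near sample 1000
  fs <- 256
  x <- numeric(2560)
  x[1001:1512] <- sin(2 * pi * 10 * (0:511) / fs)
  rec <- recording(matrix(rep(x, 8), nrow = 8, byrow = TRUE))
  filt <- filter_recording(rec, band_spec(4, 14))
  energy_before <- sum(filt$signals[1, 1:900]^2)
  energy_after <- sum(filt$signals[1, 1050:1500]^2)
  expect_lt(energy_before, 0.01 * energy_after)
})

test_that("epoch extraction slices the half-open stimulus-locked window", {
  fs <- 256
  ramp <- matrix(rep(seq_len(2560), each = 8), nrow = 8)
  bands <- list(
    band_4_14 = recording(ramp), band_20_40 = recording(2 * ramp),
    band_4_40 = recording(3 * ramp))
  ep0 <- extract_epoch(bands, list(onset_sample = 0L))
  expect_equal(ep0$X_4_14[1, ], as.numeric(1:204))
  expect_equal(ep0$X_20_40[3, ], as.numeric(2 * (1:204)))

  ep_a <- extract_epoch(bands, list(onset_sample = 100L))
  ep_b <- extract_epoch(bands, list(onset_sample = 100L))
  expect_identical(ep_a$X_4_40, ep_b$X_4_40)

  # onset + 204 == length is valid; one further overruns
  expect_silent(extract_epoch(bands, list(onset_sample = 2356L)))
  expect_bmi_error(extract_epoch(bands, list(onset_sample = 2357L)),
                   "bmi_range_error")
})

test_that("extracting a wide window and trimming equals direct extraction", {
  set.seed(7)
  rec <- recording(matrix(rnorm(8 * 2560), 8, 2560))
  bands <- filter_bands(rec)
  direct <- extract_epoch(bands, list(onset_sample = 600L))
  shift <- 40L
  wide <- extract_epoch(bands, list(onset_sample = 600L - shift),
                        epoch_ms = (204 + shift) / 256 * 1000)
  trimmed <- wide$X_4_40[, (shift + 1):(shift + 204)]
  expect_lt(max(abs(trimmed - direct$X_4_40)), 1e-6)
})

test_that("quality metrics match direct evaluation of their formulas", {
  fs <- 256
  t <- (0:203) / fs
  # 60 uV 10 Hz sine on every channel: comfortably valid
  X <- matrix(rep(60 * sin(2 * pi * 10 * t), 8), nrow = 8, byrow = TRUE)
  q <- assess_quality(epoch_from_matrices(X))
  # direct evaluation oracle
  vpp_o <- apply(X, 1, function(x) max(x) - min(x))
  sd_o <- apply(X, 1, function(x) {
    mu <- sum(x) / length(x)
    sqrt(sum((x - mu)^2) / (length(x) - 1))
  })
  expect_equal(q$v_pp, vpp_o)
  expect_equal(q$sigma, sd_o)
  expect_lt(abs(q$sigma[1] - 60 / sqrt(2)), 1.5)  # ~A/sqrt(2) over ~8 cycles
  expect_true(all(q$v_pp < 200) && all(q$sigma < 50))
  expect_true(all(q$power_ratio == 0))
  expect_equal(q$verdict, "valid")
})

test_that("any channel crossing a rejection threshold flags the epoch", {
  X <- matrix(0, 8, 204)
  X[5, 77] <- 250  # single 250 uV spike on one channel
  q <- assess_quality(epoch_from_matrices(X))
  expect_gte(q$v_pp[5], 200)
  expect_equal(q$verdict, "artifact")

  # power-ratio rule: epoch dominated by 20-40 Hz content
  t <- (0:203) / 256
  hi <- matrix(rep(10 * sin(2 * pi * 30 * t), 8), nrow = 8, byrow = TRUE)
  q2 <- assess_quality(epoch_from_matrices(X_4_40 = hi, X_20_40 = hi))
  expect_true(all(q2$power_ratio >= 0.7))
  expect_equal(q2$verdict, "artifact")

  # zero-power epoch: degenerate denominator is an artifact by definition
  q3 <- assess_quality(epoch_from_matrices(matrix(0, 8, 204)))
  expect_equal(q3$v_pp, rep(0, 8))
  expect_equal(q3$sigma, rep(0, 8))
  expect_true(all(is.nan(q3$power_ratio)))
  expect_equal(q3$verdict, "artifact")
})

test_that("quality assessment commutes with channel reordering", {
  set.seed(3)
  X440 <- matrix(rnorm(8 * 204, sd = 20), 8, 204)
  X2040 <- matrix(rnorm(8 * 204, sd = 5), 8, 204)
  q <- assess_quality(epoch_from_matrices(X440, X2040))
  perm <- sample(8)
  qp <- assess_quality(epoch_from_matrices(X440[perm, ], X2040[perm, ]))
  expect_equal(qp$v_pp, q$v_pp[perm])
  expect_equal(qp$sigma, q$sigma[perm])
  expect_equal(qp$power_ratio, q$power_ratio[perm])
  expect_equal(qp$verdict, q$verdict)
})

test_that("power ratio stays within [0, 1 + eps] on band-filtered signals", {
  set.seed(11)
  rec <- recording(matrix(rnorm(8 * 2560, sd = 10), 8, 2560))
  bands <- filter_bands(rec)
  for (onset in c(300L, 700L, 1500L)) {
    q <- assess_quality(extract_epoch(bands, list(onset_sample = onset)))
    expect_true(all(q$power_ratio >= 0))
    expect_true(all(q$power_ratio <= 1.05))
  }
})

test_that("decimation takes every fourth sample starting at the onset", {
  const <- epoch_from_matrices(matrix(0.1, 8, 204),
                               X_4_14 = matrix(7, 8, 204))
  d <- downsample_epoch(const)
  expect_equal(dim(d$Y), c(8L, 51L))
  expect_true(all(d$Y == 7))

  idx_mat <- matrix(rep(0:203, each = 8), nrow = 8)
  ep <- epoch_from_matrices(matrix(0.1, 8, 204), X_4_14 = idx_mat)
  expect_equal(downsample_epoch(ep)$Y[1, ], as.numeric(seq(0, 200, by = 4)))

  set.seed(5)
  X <- matrix(rnorm(8 * 204), 8, 204)
  ep2 <- epoch_from_matrices(matrix(rnorm(8 * 204, sd = 1), 8, 204),
                             X_4_14 = X)
  Y <- downsample_epoch(ep2)$Y
  for (k in seq_len(51)) expect_identical(Y[, k], X[, 4 * (k - 1) + 1])
})

test_that("downsampling an artifact-flagged epoch is a contract violation", {
  X <- matrix(0, 8, 204); X[1, 1] <- 300
  expect_bmi_error(downsample_epoch(epoch_from_matrices(X)),
                   "bmi_contract_error")
})
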