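feed <- function(state, events) {
  # events: data.frame(option_id, label); returns decisions + final state
  decisions <- list()
  for (i in seq_len(nrow(events))) {
    res <- controller_update(state, events$option_id[i], events$label[i])
    state <- res$state
    decisions[[i]] <- res$decision
  }
  list(state = state, decisions = decisions)
}

test_that("a consistently-targeted option is selected on its fifth valid epoch", {
  # round-robin flashing, option 2 always labeled target, others non-target
  rounds <- do.call(rbind, lapply(1:6, function(r) {
    data.frame(option_id = 0:5,
               label = ifelse(0:5 == 2, "target", "non-target"))
  }))
  out <- feed(new_controller(), rounds)
  kinds <- vapply(out$decisions, `[[`, character(1), "kind")
  first_sel <- which(kinds == "select")[1]
  # option 2 gets its 5th buffered label on the 5th round's option-2 flash
  expect_equal(first_sel, 4 * 6 + 3)
  expect_equal(out$decisions[[first_sel]]$option_id, 2L)
})

test_that("no selection fires without target evidence or below min_epochs", {
  all_nt <- data.frame(option_id = rep(0:5, 20), label = "non-target")
  out <- feed(new_controller(), all_nt)
  expect_true(all(vapply(out$decisions, `[[`, character(1), "kind") == "none"))

  # a buffer ending at 4 target / 6 non-target = 40% < 70%: never selected
  # (interleaved so no prefix of >= 5 epochs reaches 70% either)
  mixed <- data.frame(option_id = 3,
                      label = c(rep(c("non-target", "target"), 4),
                                "non-target", "non-target"))
  out2 <- feed(new_controller(), mixed)
  expect_true(all(vapply(out2$decisions, `[[`, character(1), "kind") == "none"))

  # fewer than 5 valid epochs can never select, whatever the labels
  four <- data.frame(option_id = 1, label = rep("target", 4))
  out3 <- feed(new_controller(), four)
  expect_true(all(vapply(out3$decisions, `[[`, character(1), "kind") == "none"))
})

test_that("artifact labels are discarded and do not enter buffers", {
  ev <- data.frame(option_id = c(1, 1, 1, 1, 1, 1),
                   label = c("target", "artifact", "target", "artifact",
                             "target", "target"))
  out <- feed(new_controller(), ev)
  expect_equal(out$state$discarded, 2L)
  expect_equal(length(out$state$buffers[[2]]), 4L)  # 4 valid epochs only
  kinds <- vapply(out$decisions, `[[`, character(1), "kind")
  expect_true(all(kinds == "none"))
})

test_that("default thresholds make the selection unique (exhaustive check)", {
  # all buffer contents for two options with window 10: an option at >= 70%
  # target is at <= 30% non-target, so it vetoes any other selection
  cfg <- controller_config()
  eligible <- function(n, t) n >= cfg$min_epochs &&
    t / n >= cfg$target_threshold
  vetoes <- function(n, t) n > 0 && (n - t) / n < cfg$nontarget_threshold
  both <- 0L
  for (n1 in 0:10) for (t1 in 0:n1) for (n2 in 0:10) for (t2 in 0:n2) {
    sel1 <- eligible(n1, t1) && !vetoes(n2, t2)
    sel2 <- eligible(n2, t2) && !vetoes(n1, t1)
    if (sel1 && sel2) both <- both + 1L
  }
  expect_equal(both, 0L)
})

test_that("the controller is a pure function of the label stream", {
  set.seed(40)
  ev <- data.frame(option_id = sample(0:5, 200, replace = TRUE),
                   label = sample(c("target", "non-target", "artifact"),
                                  200, replace = TRUE, prob = c(.3, .6, .1)))
  k1 <- vapply(feed(new_controller(), ev)$decisions, `[[`,
               character(1), "kind")
  k2 <- vapply(feed(new_controller(), ev)$decisions, `[[`,
               character(1), "kind")
  expect_identical(k1, k2)
})

test_that("run_attempt reports the engineered selection time", {
  # option 1 flashes at 1.2, 2.25, 3.3, 4.35, 5.4 s, always target;
  # every other option is non-target: selection fires exactly at 5.4 s
  times1 <- c(1.2, 2.25, 3.3, 4.35, 5.4)
  others <- expand.grid(option_id = c(0, 2, 3, 4, 5), rep = 1:5)
  stream <- rbind(
    data.frame(time_s = times1, option_id = 1, label = "target"),
    data.frame(time_s = seq(0.15, by = 0.15, length.out = nrow(others)),
               option_id = others$option_id, label = "non-target"))
  stream <- stream[order(stream$time_s), ]
  att <- run_attempt(stream)
  expect_equal(att$kind, "select")
  expect_equal(att$option_id, 1)
  expect_equal(att$selection_time_s, 5.4)
})

test_that("attempts without evidence time out", {
  empty <- data.frame(time_s = numeric(0), option_id = integer(0),
                      label = character(0))
  att <- run_attempt(empty)
  expect_equal(att$kind, "timeout")
  expect_true(is.na(att$selection_time_s))

  # random coin-flip labels: both outcomes occur over many seeds
  kinds <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 200
    stream <- data.frame(
      time_s = seq(0.15, by = 0.15, length.out = n),
      option_id = sample(0:5, n, replace = TRUE),
      label = sample(c("target", "non-target"), n, replace = TRUE))
    run_attempt(stream)$kind
  }, character(1))
  expect_true(all(c("select", "timeout") %in% kinds))

  expect_bmi_error(
    run_attempt(data.frame(time_s = c(2, 1), option_id = 0:1,
                           label = "target")),
    "bmi_validation_error")
})

test_that("selected options map to the documented finger movements", {
  for (o in 0:4) {
    plan <- plan_movement(o)
    expect_equal(plan$actuators,
                 c("thumb", "index", "middle", "ring", "little")[o + 1])
    expect_equal(plan$duration_s, 4)
  }
  all5 <- plan_movement(5)
  expect_equal(length(all5$actuators), 5L)
  expect_bmi_error(plan_movement(7), "bmi_parameter_error")

  frames <- movement_frames(plan_movement(0), rate_hz = 10)
  expect_equal(nrow(frames), 41L)
  expect_equal(frames$thumb[1], 0)
  expect_lt(abs(max(frames$thumb) - 1), 1e-9)
  expect_true(all(frames$index == 0))
})
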