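# Binary-SVM step counting and accuracy aggregation.

# stub detectors: classify windows from the features alone
stub_detector <- function(fun, cls) {
  obj <- structure(list(fun = fun), class = cls)
  registerS3method("predict", cls, function(object, newdata, ...) {
    x <- if (inherits(newdata, "feature_matrix")) newdata$x else newdata
    object$fun(x)
  })
  obj
}

test_that("step accuracy reproduces the worked pooled example", {
  expect_equal(step_accuracy(39 + 6 + 20, 45 + 6 + 24), 100 * (1 - 10 / 75))
  expect_equal(round(step_accuracy(65, 75), 2), 86.67)
  expect_equal(step_accuracy(123, 123), 100)
  expect_equal(step_accuracy(50, 40), 75)
  expect_error(step_accuracy(5, 0), "> 0")
})

test_that("step accuracy is symmetric and maximal only at equality", {
  set.seed(4)
  for (rep_i in 1:50) {
    actual <- sample(1:500, 1)
    d <- sample(0:actual, 1)
    expect_equal(
      step_accuracy(actual + d, actual),
      step_accuracy(actual - d, actual)
    )
    if (d > 0) expect_lt(step_accuracy(actual + d, actual), 100)
  }
})

test_that("cohort aggregation separates pooled and mean accuracy", {
  rep_out <- cohort_step_report(data.frame(
    animal_id = c("C8", "C9", "C10"),
    identified = c(39, 6, 20),
    actual = c(45, 6, 24)
  ))
  expect_equal(round(rep_out$pooled_accuracy_pct, 2), 86.67)
  expect_equal(rep_out$mean_accuracy_pct, 90)
  # all perfect -> both 100; single animal -> pooled equals mean
  perfect <- cohort_step_report(data.frame(
    animal_id = c("C1", "C2"), identified = c(10, 20), actual = c(10, 20)
  ))
  expect_equal(perfect$pooled_accuracy_pct, 100)
  expect_equal(perfect$mean_accuracy_pct, 100)
  single <- cohort_step_report(data.frame(
    animal_id = "C1", identified = 37, actual = 40
  ))
  expect_equal(single$pooled_accuracy_pct, single$mean_accuracy_pct)
  expect_error(cohort_step_report(data.frame()), "no per-animal")
})

test_that("an always-negative detector counts zero steps", {
  ds <- simulate_dataset(sim_config(), 120, seed = 1)
  det <- stub_detector(function(x) rep(FALSE, nrow(x)), "cc_stub_neg")
  ev <- count_steps(det, ds$stream)
  expect_equal(ev$step_count, 0L)
  expect_equal(nrow(ev$runs), 0L)
})

test_that("isolated positive windows form singleton runs under per_window", {
  cfg <- sim_config(rest_noise_g = 0, imu_noise_g = 0)
  # 6 isolated 1-s walking bursts in 60 s of standing rest
  segs <- data.frame(
    start_s = c(0, 5, 6, 15, 16, 25, 26, 35, 36, 45, 46, 55, 56),
    end_s = c(5, 6, 15, 16, 25, 26, 35, 36, 45, 46, 55, 56, 60),
    behavior = rep(c("standing_resting", "walking"), length.out = 13)
  )
  sim <- synthesize_imu(as_schedule(segs), cfg, seed = 1)
  det <- stub_detector(function(x) x[, "az_F2"] > 0.01, "cc_stub_var")
  ev <- count_steps(det, sim$stream, rule = "per_window")
  expect_equal(ev$step_count, 6L)
  expect_equal(nrow(ev$runs), 6L)
  expect_true(all(ev$runs$end_s - ev$runs$start_s == 1))
  # per_run counts each burst once as well
  expect_equal(count_steps(det, sim$stream, rule = "per_run")$step_count, 6L)
  # gap merging collapses runs separated by short negative stretches
  ev_merge <- count_steps(det, sim$stream,
    rule = "per_run",
    merge_gap_windows = 20
  )
  expect_lt(nrow(ev_merge$runs), 6L)
})

test_that("counts are invariant to prepending whole windows of rest", {
  cfg <- sim_config(rest_noise_g = 0, imu_noise_g = 0)
  segs <- as_schedule(data.frame(
    start_s = c(0, 20), end_s = c(20, 30),
    behavior = c("standing_resting", "walking")
  ))
  sim <- synthesize_imu(segs, cfg, seed = 1)
  det <- stub_detector(function(x) x[, "az_F2"] > 0.01, "cc_stub_var2")
  base_count <- count_steps(det, sim$stream)$step_count
  # same signal with 10 extra seconds of rest up front
  segs2 <- as_schedule(data.frame(
    start_s = c(0, 30), end_s = c(30, 40),
    behavior = c("standing_resting", "walking")
  ))
  sim2 <- synthesize_imu(segs2, cfg, seed = 1)
  expect_equal(count_steps(det, sim2$stream)$step_count, base_count)
  expect_gt(base_count, 0L)
})

test_that("a trained detector recognises held-out walking windows", {
  cfg <- sim_config()
  train_fm <- cohort_features(2, 1200, 1, base_seed = 20)
  det <- train_step_detector(train_fm, seed = 1)
  ds <- simulate_dataset(cfg, 1200, seed = 31)
  ws <- segment_windows(ds$stream, ds$schedule, length_s = 1)
  fm <- build_feature_matrix(ws)
  pred <- predict(det, fm)
  truth <- fm$label == "walking"
  expect_gt(sum(truth), 0)
  sens <- 100 * sum(pred & truth) / sum(truth)
  prec <- 100 * sum(pred & truth) / sum(pred)
  expect_gt(sens, 90)
  expect_gt(prec, 90)
  # determinism and degenerate input
  det2 <- train_step_detector(train_fm, seed = 1)
  expect_identical(predict(det2, fm), pred)
  bad <- fake_feature_matrix(train_fm$x, rep("walking", nrow(train_fm$x)))
  expect_error(train_step_detector(bad), "both step and non-step")
})

test_that("step counts are recovered on a 15-minute trace with 20 true steps", {
  cfg <- sim_config()
  # walking time chosen so exactly 20 gait cycles occur (20 / 1.5 s of gait)
  walk_len <- 20 / cfg$gait_frequency_hz
  segs <- as_schedule(data.frame(
    start_s = c(0, 300, 300 + walk_len),
    end_s = c(300, 300 + walk_len, 900),
    behavior = c("grazing", "walking", "standing_resting")
  ))
  sim <- synthesize_imu(segs, cfg, seed = 17)
  expect_length(sim$step_times_s, 20L)
  det <- train_step_detector(cohort_features(2, 1200, 1, base_seed = 20), seed = 1)
  ev <- count_steps(det, sensor_stream(sim$stream$t_s, sim$stream$channels))
  expect_lte(abs(ev$step_count - 20), 3)
})

test_that("a sub-window stream yields zero events with a warning", {
  cfg <- sim_config()
  sim <- synthesize_imu(one_bout("walking", 10), cfg, seed = 1)
  short <- sensor_stream(sim$stream$t_s[1:10], sim$stream$channels[1:10, ])
  det <- stub_detector(function(x) rep(TRUE, nrow(x)), "cc_stub_pos")
  expect_warning(ev <- count_steps(det, short, window_s = 1), "shorter")
  expect_equal(ev$step_count, 0L)
})
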