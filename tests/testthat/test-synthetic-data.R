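# Synthetic collar-data generator: schedules, IMU regimes, temperature.

test_that("schedules partition the time axis with valid labels", {
  cfg <- sim_config()
  for (seed in 1:5) {
    sched <- generate_schedule(cfg, duration_s = 600, seed = seed)
    expect_equal(sched$start_s[1], 0)
    expect_equal(sched$end_s[nrow(sched)], 600)
    if (nrow(sched) > 1) {
      expect_equal(sched$start_s[-1], sched$end_s[-nrow(sched)])
    }
    expect_true(all(sched$end_s > sched$start_s))
    expect_true(all(sched$behavior %in% behavior_levels()))
  }
})

test_that("posture changes are bridged by the matching transition class", {
  sched <- generate_schedule(sim_config(), duration_s = 3600, seed = 3)
  lab <- sched$behavior
  for (i in seq_len(nrow(sched) - 1)) {
    a <- lab[i]
    b <- lab[i + 1]
    if (a == "lying_resting") expect_equal(b, "lie_to_stand")
    if (b == "lying_resting") expect_equal(a, "stand_to_lie")
  }
  trans <- sched[lab %in% c("stand_to_lie", "lie_to_stand"), ]
  # non-clipped transitions last exactly transition_duration_s
  full <- trans[trans$end_s < 3600, ]
  expect_true(all(abs(full$end_s - full$start_s - 3) < 1e-9))
})

test_that("an absorbing transition matrix yields a single bout", {
  tm <- matrix(0, 7, 7, dimnames = list(behavior_levels(), behavior_levels()))
  tm[, "standing_resting"] <- 1
  cfg <- sim_config(transition_matrix = tm)
  sched <- generate_schedule(cfg, duration_s = 600, seed = 2)
  expect_equal(nrow(sched), 1L)
  expect_equal(sched$behavior, "standing_resting")
})

test_that("schedule generation is deterministic for a fixed seed", {
  cfg <- sim_config()
  s1 <- generate_schedule(cfg, 600, seed = 7)
  s2 <- generate_schedule(cfg, 600, seed = 7)
  expect_identical(s1, s2)
  s3 <- generate_schedule(cfg, 600, seed = 8)
  expect_false(identical(s1, s3))
})

test_that("a non-stochastic transition matrix is rejected", {
  tm <- default_transition_matrix()
  tm[1, 1] <- 0.5
  expect_error(sim_config(transition_matrix = tm), "sum to 1")
})

test_that("walking emits one true step event per gait cycle", {
  cfg <- sim_config() # 1.5 Hz gait
  sched <- one_bout("walking", 10)
  sim <- synthesize_imu(sched, cfg, seed = 1)
  expect_length(sim$step_times_s, 15L)
  # per-leg convention doubles the event count
  cfg2 <- sim_config(steps_per_cycle = 2)
  expect_length(synthesize_imu(sched, cfg2, seed = 1)$step_times_s, 30L)
})

test_that("true step events always fall inside walking bouts", {
  cfg <- sim_config()
  for (seed in 1:3) {
    sched <- generate_schedule(cfg, 1800, seed = seed)
    sim <- synthesize_imu(sched, cfg, seed = seed)
    walk <- sched[sched$behavior == "walking", ]
    inside <- vapply(
      sim$step_times_s,
      function(ts) any(ts >= walk$start_s & ts < walk$end_s),
      logical(1)
    )
    expect_true(all(inside))
    # count matches whole gait cycles of total walking time
    expect_equal(
      length(sim$step_times_s),
      sum(floor((walk$end_s - walk$start_s) * cfg$gait_frequency_hz +
        0.75 - 1e-9))
    )
  }
})

test_that("noiseless lying rest is pure gravity with unit magnitude", {
  cfg <- sim_config(rest_noise_g = 0, imu_noise_g = 0)
  sim <- synthesize_imu(one_bout("lying_resting", 30), cfg, seed = 1)
  acc <- sim$stream$channels[, c("ax", "ay", "az")]
  expect_true(all(abs(sqrt(rowSums(acc^2)) - 1) < 1e-12))
  expect_true(all(abs(acc[, "ay"] - 1) < 1e-12))
})

test_that("noiseless walking matches its closed-form signal model", {
  cfg <- sim_config(rest_noise_g = 0, imu_noise_g = 0)
  sim <- synthesize_imu(one_bout("walking", 10), cfg, seed = 1)
  t <- sim$stream$t_s
  ph <- 2 * pi * cfg$gait_frequency_hz * t
  expect_equal(sim$stream$channels[, "az"], 1 + cfg$gait_amplitude_g * sin(ph))
  expect_equal(sim$stream$channels[, "ax"], 0.5 * cfg$gait_amplitude_g * cos(ph))
})

test_that("walking accelerometer variance exceeds standing-rest variance", {
  cfg <- sim_config()
  vw <- apply(
    synthesize_imu(one_bout("walking", 60), cfg, seed = 5)$stream$channels[, 1:3],
    2, var
  )
  vs <- apply(
    synthesize_imu(
      one_bout("standing_resting", 60), cfg,
      seed = 5
    )$stream$channels[, 1:3],
    2, var
  )
  expect_true(all(vw[c("ax", "az")] > vs[c("ax", "az")]))
  expect_gt(sum(vw), sum(vs))
})

test_that("IMU synthesis is deterministic and rejects empty schedules", {
  cfg <- sim_config()
  sched <- generate_schedule(cfg, 120, seed = 1)
  a <- synthesize_imu(sched, cfg, seed = 4)
  b <- synthesize_imu(sched, cfg, seed = 4)
  expect_identical(a$stream$channels, b$stream$channels)
  expect_identical(a$step_times_s, b$step_times_s)
  expect_error(
    synthesize_imu(sched[0, ], cfg, seed = 1),
    "empty"
  )
})

test_that("noiseless temperature equals baseline minus skin offset", {
  cfg <- sim_config(
    temp_noise_sd_c = 0, artifact_rate_per_min = 0,
    temp_drift_amplitude_c = 0
  )
  tr <- synthesize_temperature(cfg, 600, seed = 1)
  expect_true(all(abs(tr$temp_c - 37.2) < 1e-12))
  expect_equal(tr$rectal_baseline_c, 38.3)
})

test_that("default skin temperature stays mostly in the physiological band", {
  tr <- synthesize_temperature(sim_config(), 3 * 3600, seed = 1)
  frac <- mean(tr$temp_c >= 36.5 & tr$temp_c <= 37.5)
  expect_gt(frac, 0.9)
})

test_that("temperature synthesis is deterministic for a fixed seed", {
  cfg <- sim_config()
  expect_identical(
    synthesize_temperature(cfg, 600, seed = 9)$temp_c,
    synthesize_temperature(cfg, 600, seed = 9)$temp_c
  )
})

test_that("cohorts carry ids C1..Cn and reproduce from the base seed", {
  cfg <- sim_config()
  cohort <- generate_cohort(10, cfg, 60, base_seed = 0)
  expect_length(cohort, 10L)
  expect_equal(
    vapply(cohort, function(d) d$animal_id, character(1)),
    paste0("C", 1:10)
  )
  single <- generate_cohort(1, cfg, 60, base_seed = 0)
  expect_length(single, 1L)
  expect_identical(single[[1]]$stream$channels, cohort[[1]]$stream$channels)
  again <- generate_cohort(2, cfg, 60, base_seed = 0)
  expect_identical(again[[2]]$temperature$temp_c, cohort[[2]]$temperature$temp_c)
  # streams differ between animals
  expect_false(identical(
    cohort[[1]]$stream$channels,
    cohort[[2]]$stream$channels
  ))
})
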