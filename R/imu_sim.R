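# Deterministic signal models per behaviour.  Accelerometer channels report
# specific force in g: upright posture puts gravity on +z, lying rotates it
# onto +y, head-down postures pitch it towards -x.

orientation_of <- function(label) {
  switch(label,
    walking = ,
    standing_resting = c(0, 0, 1),
    feeding = c(-sin(20 * pi / 180), 0, cos(20 * pi / 180)),
    grazing = c(-sin(50 * pi / 180), 0, cos(50 * pi / 180)),
    lying_resting = c(0, 1, 0),
    stand_to_lie = c(0, 1, 0),
    lie_to_stand = c(0, 0, 1),
    stopf("unknown behavior label: %s", label)
  )
}

MAG_HEADING <- c(0.4, 0.1, -0.3) # constant heading term on mx/my/mz
GYRO_NOISE_SCALE <- 10 # gyro noise sd = accel noise sd x this, in dps

#' Synthesize a 9-channel IMU stream from a behaviour schedule
#'
#' Renders each scheduled bout with its deterministic signal model plus
#' Gaussian noise: resting classes carry the posture's gravity vector and
#' noise of sd `rest_noise_g`; walking adds a periodic gait component at
#' `gait_frequency_hz` (amplitude `gait_amplitude_g` on z, half on x) and
#' emits one true step event per gait cycle (at the vertical-acceleration
#' peak); grazing and feeding add a slow head-bob oscillation; posture
#' transitions ramp the gravity orientation linearly across the bout.
#' Gyroscope channels carry matching angular-rate oscillations (noise sd is
#' ten times the accelerometer sd, in deg/s); magnetometer channels are a
#' constant heading term plus noise.
#'
#' @param schedule A [generate_schedule()] result (or equivalent intervals).
#' @param config A [sim_config()].
#' @param seed Integer seed; output is bit-reproducible for a fixed seed.
#' @return A list with `stream` (a [sensor_stream()]) and `step_times_s`
#'   (sorted true step-event times, all inside walking bouts).
#' @export
#' @examples
#' cfg <- sim_config()
#' sched <- generate_schedule(cfg, 120, seed = 1)
#' sim <- synthesize_imu(sched, cfg, seed = 1)
#' sim$stream
synthesize_imu <- function(schedule, config, seed = config$seed) {
  validate_sim_config(config)
  if (nrow(schedule) == 0L) stopf("schedule is empty")
  dur <- attr(schedule, "total_duration_s")
  rate <- config$sampling_rate_hz
  n <- round(dur * rate)
  if (n < 1L) stopf("schedule too short for one sample at %g Hz", rate)
  t <- (seq_len(n) - 1L) / rate

  X <- matrix(0, n, 9L, dimnames = list(NULL, imu_channel_names()))
  X[, "mx"] <- MAG_HEADING[1L]
  X[, "my"] <- MAG_HEADING[2L]
  X[, "mz"] <- MAG_HEADING[3L]
  sd_acc <- numeric(n)
  step_times <- numeric(0)

  seg_of <- findInterval(t, schedule$start_s)
  for (i in seq_len(nrow(schedule))) {
    idx <- which(seg_of == i)
    if (!length(idx)) next
    lab <- schedule$behavior[i]
    a <- schedule$start_s[i]
    b <- schedule$end_s[i]
    tt <- t[idx] - a
    if (lab %in% c("stand_to_lie", "lie_to_stand")) {
      from <- if (i > 1L) orientation_of(schedule$behavior[i - 1L]) else orientation_of("standing_resting")
      to <- if (i < nrow(schedule)) orientation_of(schedule$behavior[i + 1L]) else orientation_of(lab)
      w <- tt / (b - a)
      for (k in 1:3) X[idx, k] <- (1 - w) * from[k] + w * to[k]
      # angular rate about x matching the 90 degree posture ramp
      X[idx, "gx"] <- (if (lab == "stand_to_lie") 1 else -1) * 90 / (b - a)
      sd_acc[idx] <- config$imu_noise_g
    } else {
      ori <- orientation_of(lab)
      for (k in 1:3) X[idx, k] <- ori[k]
      if (lab == "walking") {
        ph <- 2 * pi * config$gait_frequency_hz * tt
        X[idx, "az"] <- X[idx, "az"] + config$gait_amplitude_g * sin(ph)
        X[idx, "ax"] <- X[idx, "ax"] + 0.5 * config$gait_amplitude_g * cos(ph)
        X[idx, "gy"] <- 10 * sin(ph)
        step_times <- c(step_times, step_times_for_bout(a, b, config))
        sd_acc[idx] <- config$imu_noise_g
      } else if (lab %in% c("grazing", "feeding")) {
        ph <- 2 * pi * config$headbob_frequency_hz * tt
        X[idx, "az"] <- X[idx, "az"] + config$headbob_amplitude_g * sin(ph)
        X[idx, "ax"] <- X[idx, "ax"] + 0.5 * config$headbob_amplitude_g * cos(ph)
        X[idx, "gy"] <- 20 * sin(ph)
        sd_acc[idx] <- config$imu_noise_g
      } else {
        sd_acc[idx] <- config$rest_noise_g
      }
    }
  }

  with_seed(seed + SEED_OFFSET_IMU, {
    sd_mat <- cbind(
      sd_acc, sd_acc, sd_acc,
      GYRO_NOISE_SCALE * sd_acc, GYRO_NOISE_SCALE * sd_acc, GYRO_NOISE_SCALE * sd_acc,
      sd_acc, sd_acc, sd_acc
    )
    X <- X + matrix(stats::rnorm(n * 9L), n, 9L) * sd_mat
  })

  list(
    stream = sensor_stream(t, X, sample_rate_hz = rate),
    step_times_s = sort(step_times)
  )
}

# one true step event per gait cycle, at the vertical-acceleration peak
# (phase pi/2); a second per-leg event at phase 3*pi/2 when steps_per_cycle = 2
step_times_for_bout <- function(start_s, end_s, config) {
  f <- config$gait_frequency_hz
  offs <- if (config$steps_per_cycle == 2L) c(0.25, 0.75) else 0.25
  out <- numeric(0)
  for (o in offs) {
    k <- seq.int(0L, max(0, ceiling((end_s - start_s) * f)))
    tt <- start_s + (k + o) / f
    out <- c(out, tt[tt < end_s])
  }
  sort(out)
}
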