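#' Simulation configuration for synthetic collar-sensor data
#'
#' Bundles every knob of the synthetic data generator: IMU and temperature
#' sampling rates, the walking-gait and head-bob signal models, the skin
#' temperature model (baseline offset from the rectal reference, slow drift,
#' AR(1) noise, transient artifact spikes), behaviour dwell times and the
#' semi-Markov transition matrix.
#'
#' The accelerometer reports specific force in g with upright posture giving
#' +z of about 1 g; lying rotates gravity onto +y.  Walking carries a periodic
#' gait component at `gait_frequency_hz` with one true step event per gait
#' cycle (set `steps_per_cycle = 2` for a per-leg convention); grazing and
#' feeding carry a slow head-bob oscillation; resting classes carry noise
#' only; posture transitions ramp the gravity orientation linearly over
#' `transition_duration_s`.
#'
#' @param sampling_rate_hz IMU sampling rate in Hz (default 20).
#' @param temp_rate_hz Skin-temperature sampling rate in Hz (default 1).
#' @param gait_frequency_hz Steps per second while walking (default 1.5).
#' @param gait_amplitude_g Peak gait acceleration in g (default 0.4).
#' @param rest_noise_g Accelerometer noise sd during resting classes (default 0.02).
#' @param imu_noise_g Accelerometer noise sd during active classes (default 0.05).
#' @param headbob_frequency_hz Head-bob frequency during grazing/feeding (default 0.35).
#' @param headbob_amplitude_g Head-bob acceleration amplitude in g (default 0.15).
#' @param rectal_baseline_c Rectal reference temperature in deg C (default 38.3).
#' @param skin_offset_c Mean rectal-minus-skin offset in deg C (default 1.1).
#' @param temp_noise_sd_c Stationary sd of the AR(1) temperature noise (default 0.15).
#' @param temp_drift_amplitude_c Amplitude of the slow sinusoidal drift (default 0.1).
#' @param temp_drift_period_s Period of the drift in seconds (default 3600).
#' @param ar1_phi AR(1) coefficient of the temperature noise (default 0.9).
#' @param artifact_rate_per_min Poisson rate of transient artifact spikes (default 0.5).
#' @param artifact_magnitude_c Artifact spike magnitude in deg C, applied with
#'   random sign (default 1.0).
#' @param transition_duration_s Duration of a posture transition (default 3).
#' @param dwell_mean_s Named vector of mean dwell times (s) for the five main
#'   behaviours.
#' @param transition_matrix Row-stochastic 7x7 matrix over the full ethogram
#'   (rows/columns in `behavior_levels()` order).
#' @param steps_per_cycle 1 (default) or 2 true step events per gait cycle.
#' @param seed Default integer seed for generators that are not given one.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [generate_schedule()], [synthesize_imu()],
#'   [synthesize_temperature()], [generate_cohort()]
#' @export
#' @examples
#' cfg <- sim_config()
#' cfg$gait_frequency_hz
sim_config <- function(sampling_rate_hz = 20,
                       temp_rate_hz = 1,
                       gait_frequency_hz = 1.5,
                       gait_amplitude_g = 0.4,
                       rest_noise_g = 0.02,
                       imu_noise_g = 0.05,
                       headbob_frequency_hz = 0.35,
                       headbob_amplitude_g = 0.15,
                       rectal_baseline_c = 38.3,
                       skin_offset_c = 1.1,
                       temp_noise_sd_c = 0.15,
                       temp_drift_amplitude_c = 0.1,
                       temp_drift_period_s = 3600,
                       ar1_phi = 0.9,
                       artifact_rate_per_min = 0.5,
                       artifact_magnitude_c = 1.0,
                       transition_duration_s = 3,
                       dwell_mean_s = c(
                         feeding = 180, grazing = 180, walking = 60,
                         lying_resting = 300, standing_resting = 120
                       ),
                       transition_matrix = default_transition_matrix(),
                       steps_per_cycle = 1L,
                       seed = 1L) {
  cfg <- list(
    sampling_rate_hz = sampling_rate_hz,
    temp_rate_hz = temp_rate_hz,
    gait_frequency_hz = gait_frequency_hz,
    gait_amplitude_g = gait_amplitude_g,
    rest_noise_g = rest_noise_g,
    imu_noise_g = imu_noise_g,
    headbob_frequency_hz = headbob_frequency_hz,
    headbob_amplitude_g = headbob_amplitude_g,
    rectal_baseline_c = rectal_baseline_c,
    skin_offset_c = skin_offset_c,
    temp_noise_sd_c = temp_noise_sd_c,
    temp_drift_amplitude_c = temp_drift_amplitude_c,
    temp_drift_period_s = temp_drift_period_s,
    ar1_phi = ar1_phi,
    artifact_rate_per_min = artifact_rate_per_min,
    artifact_magnitude_c = artifact_magnitude_c,
    transition_duration_s = transition_duration_s,
    dwell_mean_s = dwell_mean_s,
    transition_matrix = transition_matrix,
    steps_per_cycle = as.integer(steps_per_cycle),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Default semi-Markov transition matrix over the ethogram
#'
#' Rows and columns follow `behavior_levels()` order.  The five main
#' behaviours transition among themselves (zero diagonal); the two transition
#' classes route deterministically to the posture they end in (`stand_to_lie`
#' to lying rest, `lie_to_stand` uniformly to the standing-family
#' behaviours).  Posture-bridging transition segments are inserted by
#' [generate_schedule()] whenever the sampled move crosses posture families.
#'
#' @return A row-stochastic 7x7 numeric matrix.
#' @export
default_transition_matrix <- function() {
  lv <- behavior_levels()
  m <- matrix(0, 7, 7, dimnames = list(lv, lv))
  m["feeding", c("grazing", "walking", "lying_resting", "standing_resting")] <-
    c(0.30, 0.30, 0.20, 0.20)
  m["grazing", c("feeding", "walking", "lying_resting", "standing_resting")] <-
    c(0.30, 0.30, 0.20, 0.20)
  m["walking", c("feeding", "grazing", "lying_resting", "standing_resting")] <-
    c(0.25, 0.25, 0.20, 0.30)
  m["lying_resting", c("feeding", "grazing", "walking", "standing_resting")] <-
    c(0.20, 0.20, 0.30, 0.30)
  m["standing_resting", c("feeding", "grazing", "walking", "lying_resting")] <-
    c(0.25, 0.25, 0.30, 0.20)
  m["stand_to_lie", "lying_resting"] <- 1
  m["lie_to_stand", c("feeding", "grazing", "walking", "standing_resting")] <- 0.25
  m
}

validate_sim_config <- function(cfg) {
  pos <- c(
    "sampling_rate_hz", "temp_rate_hz", "gait_frequency_hz",
    "headbob_frequency_hz", "transition_duration_s", "temp_drift_period_s"
  )
  for (f in pos) {
    if (!is_number(cfg[[f]]) || cfg[[f]] <= 0) stopf("%s must be a positive number", f)
  }
  nonneg <- c(
    "gait_amplitude_g", "rest_noise_g", "imu_noise_g", "headbob_amplitude_g",
    "temp_noise_sd_c", "temp_drift_amplitude_c", "artifact_rate_per_min"
  )
  for (f in nonneg) {
    if (!is_number(cfg[[f]]) || cfg[[f]] < 0) stopf("%s must be a non-negative number", f)
  }
  if (!is_number(cfg$ar1_phi) || abs(cfg$ar1_phi) >= 1) {
    stopf("ar1_phi must lie in (-1, 1)")
  }
  if (!cfg$steps_per_cycle %in% c(1L, 2L)) stopf("steps_per_cycle must be 1 or 2")
  dm <- cfg$dwell_mean_s
  if (!all(main_behaviors() %in% names(dm))) {
    stopf(
      "dwell_mean_s must name every main behavior: %s",
      paste(main_behaviors(), collapse = ", ")
    )
  }
  if (any(!is.finite(dm)) || any(dm <= 0)) stopf("dwell_mean_s values must be positive")
  tm <- cfg$transition_matrix
  if (!is.matrix(tm) || !all(dim(tm) == c(7L, 7L))) {
    stopf("transition_matrix must be a 7x7 matrix")
  }
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-9)) {
    stopf("transition_matrix rows must be non-negative and sum to 1 (within 1e-9)")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic collar-sensor configuration\n")
  cat(sprintf(
    "  IMU %g Hz | temperature %g Hz | seed %d\n",
    x$sampling_rate_hz, x$temp_rate_hz, x$seed
  ))
  cat(sprintf(
    "  gait %g Hz x %g g | head-bob %g Hz x %g g | noise %g/%g g (rest/active)\n",
    x$gait_frequency_hz, x$gait_amplitude_g, x$headbob_frequency_hz,
    x$headbob_amplitude_g, x$rest_noise_g, x$imu_noise_g
  ))
  cat(sprintf(
    "  skin temp: %.1f C baseline - %.1f C offset, AR(1) sd %.2f, drift %.2f C / %g s\n",
    x$rectal_baseline_c, x$skin_offset_c, x$temp_noise_sd_c,
    x$temp_drift_amplitude_c, x$temp_drift_period_s
  ))
  invisible(x)
}
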