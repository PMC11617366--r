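#' Construct a skin-temperature trace
#'
#' @param t_s Timestamps in seconds (uniform, increasing).
#' @param temp_c Skin temperatures in deg C.
#' @param rectal_baseline_c Rectal reference temperature in deg C (may be `NA`).
#' @param animal_id Optional animal identifier.
#' @return An object of class `temperature_trace`.
#' @export
temperature_trace <- function(t_s, temp_c, rectal_baseline_c = NA_real_,
                              animal_id = NA_character_) {
  if (length(t_s) != length(temp_c)) stopf("t_s and temp_c have different lengths")
  if (length(t_s) == 0L) stopf("temperature trace is empty")
  if (any(!is.finite(temp_c))) stopf("temp_c contains non-finite values")
  check_uniform(t_s, what = "temperature trace")
  structure(
    list(
      t_s = as.numeric(t_s), temp_c = as.numeric(temp_c),
      rectal_baseline_c = rectal_baseline_c, animal_id = animal_id
    ),
    class = "temperature_trace"
  )
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf(
    "Temperature trace%s: %d samples, %.2f-%.2f C (rectal baseline %.1f C)\n",
    if (is.na(x$animal_id)) "" else paste0(" [", x$animal_id, "]"),
    length(x$t_s), min(x$temp_c), max(x$temp_c), x$rectal_baseline_c
  ))
  invisible(x)
}

#' Synthesize an infrared skin-temperature trace
#'
#' Emulates collar-mounted infrared thermography of the neck: the skin runs
#' `skin_offset_c` below the rectal baseline, with a slow sinusoidal drift
#' (amplitude `temp_drift_amplitude_c`, period `temp_drift_period_s`),
#' stationary AR(1) measurement noise of sd `temp_noise_sd_c`, and
#' Poisson-placed transient artifact spikes of 1-3 samples (random sign,
#' magnitude `artifact_magnitude_c`) standing in for blinks, head shakes and
#' sensor-contact loss.
#'
#' @param config A [sim_config()].
#' @param duration_s Trace duration in seconds (> 0).
#' @param seed Integer seed; output is bit-reproducible for a fixed seed.
#' @param animal_id Optional animal identifier.
#' @return A [temperature_trace()] carrying the rectal baseline.
#' @export
#' @examples
#' tr <- synthesize_temperature(sim_config(), duration_s = 600, seed = 1)
#' range(tr$temp_c)
synthesize_temperature <- function(config, duration_s, seed = config$seed,
                                   animal_id = NA_character_) {
  validate_sim_config(config)
  if (!is_number(duration_s) || duration_s <= 0) stopf("duration_s must be > 0")
  rate <- config$temp_rate_hz
  n <- round(duration_s * rate)
  if (n < 1L) stopf("duration too short for one sample at %g Hz", rate)
  t <- (seq_len(n) - 1L) / rate
  base <- config$rectal_baseline_c - config$skin_offset_c
  drift <- config$temp_drift_amplitude_c * sin(2 * pi * t / config$temp_drift_period_s)
  temp <- with_seed(seed + SEED_OFFSET_TEMP, {
    noise <- if (config$temp_noise_sd_c > 0) {
      phi <- config$ar1_phi
      innov_sd <- config$temp_noise_sd_c * sqrt(1 - phi^2)
      as.numeric(stats::filter(stats::rnorm(n, sd = innov_sd), phi,
        method = "recursive",
        init = stats::rnorm(1L, sd = config$temp_noise_sd_c)
      ))
    } else {
      numeric(n)
    }
    x <- base + drift + noise
    n_art <- stats::rpois(1L, config$artifact_rate_per_min * duration_s / 60)
    if (n_art > 0L) {
      pos <- sample.int(n, n_art, replace = TRUE)
      width <- sample(1:3, n_art, replace = TRUE)
      sgn <- sample(c(-1, 1), n_art, replace = TRUE)
      for (j in seq_len(n_art)) {
        idx <- pos[j]:min(n, pos[j] + width[j] - 1L)
        x[idx] <- x[idx] + sgn[j] * config$artifact_magnitude_c
      }
    }
    x
  })
  temperature_trace(t, temp,
    rectal_baseline_c = config$rectal_baseline_c,
    animal_id = animal_id
  )
}
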