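#' Construct a 9-channel IMU sensor stream
#'
#' @param t_s Numeric vector of timestamps in seconds (uniform, increasing).
#' @param channels Numeric matrix with one row per sample and columns
#'   `ax, ay, az` (g), `gx, gy, gz` (deg/s), `mx, my, mz` (arbitrary units).
#' @param sample_rate_hz Sampling rate in Hz; inferred from `t_s` if missing.
#' @param animal_id Optional animal identifier.
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(t_s, channels, sample_rate_hz = NULL, animal_id = NA_character_) {
  channels <- as.matrix(channels)
  if (length(t_s) != nrow(channels)) stopf("t_s and channels have different lengths")
  if (ncol(channels) != 9L) stopf("channels must have 9 columns")
  colnames(channels) <- imu_channel_names()
  if (length(t_s) == 0L) stopf("sensor stream is empty")
  check_uniform(t_s, what = "sensor stream")
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- if (length(t_s) > 1L) 1 / stats::median(diff(t_s)) else 1
  }
  structure(
    list(
      t_s = as.numeric(t_s), channels = channels,
      sample_rate_hz = sample_rate_hz, animal_id = animal_id
    ),
    class = "sensor_stream"
  )
}

imu_channel_names <- function() c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf(
    "Sensor stream%s: %d samples at %.6g Hz (%.1f s), 9 channels\n",
    if (is.na(x$animal_id)) "" else paste0(" [", x$animal_id, "]"),
    length(x$t_s), x$sample_rate_hz, diff(range(x$t_s)) + 1 / x$sample_rate_hz
  ))
  invisible(x)
}
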