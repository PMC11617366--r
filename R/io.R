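# CSV exchange formats.  All sensor exchange is plain CSV with seconds-based
# float timestamps, 0-based from recording start:
#   stream:      t_s, ax_g, ay_g, az_g, gx_dps, gy_dps, gz_dps, mx, my, mz
#   temperature: t_s, temp_c
#   labels:      start_s, end_s, behavior
#   steps:       t_s

sensor_csv_columns <- function() {
  c(
    "t_s", "ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps",
    "mx", "my", "mz"
  )
}

write_plain_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_plain_csv <- function(path, required) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stopf("cannot read %s: %s", path, conditionMessage(e))
  )
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stopf("%s is missing column(s): %s", path, paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stopf("%s contains no rows", path)
  df
}

#' Write / read a 9-channel sensor stream as CSV
#'
#' @param stream A [sensor_stream()].
#' @param path CSV file path.
#' @return `write_sensor_csv` returns `path` invisibly; `read_sensor_csv`
#'   returns a [sensor_stream()] with the sample rate inferred from the
#'   timestamps.
#' @export
write_sensor_csv <- function(stream, path) {
  df <- data.frame(t_s = stream$t_s, stream$channels)
  names(df) <- sensor_csv_columns()
  write_plain_csv(df, path)
}

#' @rdname write_sensor_csv
#' @export
read_sensor_csv <- function(path) {
  df <- read_plain_csv(path, sensor_csv_columns())
  num <- as.matrix(df[, sensor_csv_columns()])
  if (any(!is.finite(num))) stopf("%s contains missing or non-numeric values", path)
  if (any(diff(df$t_s) <= 0)) stopf("%s has non-monotone timestamps", path)
  sensor_stream(df$t_s, num[, -1L, drop = FALSE])
}

#' Write / read a skin-temperature trace as CSV
#'
#' @param trace A [temperature_trace()].
#' @param path CSV file path.
#' @param rectal_baseline_c Baseline attached on read (the CSV itself only
#'   carries `t_s, temp_c`).
#' @param animal_id Animal id attached on read.
#' @return `read_temperature_csv` returns a [temperature_trace()].
#' @export
write_temperature_csv <- function(trace, path) {
  write_plain_csv(data.frame(t_s = trace$t_s, temp_c = trace$temp_c), path)
}

#' @rdname write_temperature_csv
#' @export
read_temperature_csv <- function(path, rectal_baseline_c = NA_real_,
                                 animal_id = NA_character_) {
  df <- read_plain_csv(path, c("t_s", "temp_c"))
  if (any(!is.finite(df$t_s)) || any(!is.finite(df$temp_c))) {
    stopf("%s contains missing or non-numeric values", path)
  }
  if (any(diff(df$t_s) <= 0)) stopf("%s has non-monotone timestamps", path)
  temperature_trace(df$t_s, df$temp_c,
    rectal_baseline_c = rectal_baseline_c,
    animal_id = animal_id
  )
}

#' Write / read behaviour label intervals as CSV
#'
#' Behaviour names are matched case-insensitively against the seven-class
#' ethogram; intervals must not overlap.
#'
#' @param schedule A `behavior_schedule` or data frame with `start_s`,
#'   `end_s`, `behavior`.
#' @param path CSV file path.
#' @return `read_label_csv` returns a `behavior_schedule`.
#' @export
write_label_csv <- function(schedule, path) {
  write_plain_csv(
    data.frame(
      start_s = schedule$start_s, end_s = schedule$end_s,
      behavior = schedule$behavior
    ),
    path
  )
}

#' @rdname write_label_csv
#' @export
read_label_csv <- function(path) {
  df <- read_plain_csv(path, c("start_s", "end_s", "behavior"))
  if (any(df$end_s <= df$start_s)) stopf("%s has intervals with end_s <= start_s", path)
  as_schedule(df)
}

#' Write / read ground-truth step-event times as CSV
#'
#' @param step_times_s Sorted numeric vector of step-event times.
#' @param path CSV file path.
#' @return `read_steps_csv` returns the numeric vector of times.
#' @export
write_steps_csv <- function(step_times_s, path) {
  write_plain_csv(data.frame(t_s = step_times_s), path)
}

#' @rdname write_steps_csv
#' @export
read_steps_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"t_s" %in% names(df)) stopf("%s is missing column t_s", path)
  sort(as.numeric(df$t_s))
}

#' Write a whole synthetic dataset to a directory
#'
#' Emits `<id>_stream.csv`, `<id>_temperature.csv`, `<id>_labels.csv` and
#' `<id>_steps.csv` for one animal.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisible named character vector of the four paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- dataset$animal_id
  paths <- c(
    stream = file.path(dir, paste0(id, "_stream.csv")),
    temperature = file.path(dir, paste0(id, "_temperature.csv")),
    labels = file.path(dir, paste0(id, "_labels.csv")),
    steps = file.path(dir, paste0(id, "_steps.csv"))
  )
  write_sensor_csv(dataset$stream, paths[["stream"]])
  write_temperature_csv(dataset$temperature, paths[["temperature"]])
  write_label_csv(dataset$schedule, paths[["labels"]])
  write_steps_csv(dataset$true_step_times_s, paths[["steps"]])
  invisible(paths)
}
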