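# Binary-SVM step counting: short windows are featurized exactly as in the
# behaviour pipeline, classified walk/non-walk, and step events are counted
# inside the positive spans.

#' Train the binary walking/step detector
#'
#' A binary RBF support vector machine over window features distinguishing
#' walking windows from everything else, with per-feature z-scoring fitted on
#' the training rows.
#'
#' @param features A [build_feature_matrix()] result whose labels are binary
#'   (`"walking"`/other behaviour labels, or logical, or `"step"/"nonstep"`).
#' @param hyperparams Named list: `kernel` (default `"radial"`), `cost`
#'   (default 10), `gamma` (default `1/n_features`).
#' @param seed Integer seed; training is deterministic for a fixed seed.
#' @param positive_label Label treated as the walking/step class (default
#'   `"walking"`; logical labels use `TRUE`).
#' @return An object of class `step_detector` with a `predict` method
#'   returning a logical vector (`TRUE` = walking window).
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(), 900, seed = 1)
#' fm <- build_feature_matrix(segment_windows(ds$stream, ds$schedule, length_s = 1))
#' if (sum(fm$label == "walking") > 0 && sum(fm$label != "walking") > 0) {
#'   det <- train_step_detector(fm, seed = 1)
#'   det
#' }
train_step_detector <- function(features, hyperparams = list(), seed = 1L,
                                positive_label = "walking") {
  hp <- utils::modifyList(
    list(kernel = "radial", cost = 10, gamma = NULL),
    hyperparams
  )
  y <- features$label
  keep <- !is.na(y)
  x <- features$x[keep, , drop = FALSE]
  y <- y[keep]
  pos <- if (is.logical(y)) y else y == positive_label
  if (!any(pos) || all(pos)) stopf("both step and non-step windows are required")
  yf <- factor(ifelse(pos, "step", "nonstep"), levels = c("nonstep", "step"))
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  fit <- with_seed(seed, e1071::svm(xs, yf,
    kernel = hp$kernel, cost = hp$cost,
    gamma = if (is.null(hp$gamma)) 1 / ncol(xs) else hp$gamma
  ))
  structure(
    list(fit = fit, scaler = scaler, hyperparams = hp, seed = as.integer(seed)),
    class = "step_detector"
  )
}

#' @export
predict.step_detector <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else as.matrix(newdata)
  as.character(stats::predict(object$fit, apply_scaler(x, object$scaler))) == "step"
}

#' @export
print.step_detector <- function(x, ...) {
  cat(sprintf(
    "Binary step detector: %s-kernel SVM, cost %g, %d support vectors\n",
    x$hyperparams$kernel, x$hyperparams$cost, x$fit$tot.nSV
  ))
  invisible(x)
}

#' Detect walking spans and count steps in a sensor stream
#'
#' Tiles the stream with short windows (default 1 s, non-overlapping),
#' featurizes them through the same code path as the behaviour pipeline,
#' classifies each window with the detector, and merges consecutive positive
#' windows (optionally bridging gaps of up to `merge_gap_windows`) into
#' walking runs.  Steps are then counted by the configured rule:
#'
#' * `"peaks"` (default): one step per dominant peak of the dynamic
#'   acceleration magnitude inside each run, found with a minimum peak height
#'   of half the run's RMS amplitude and a 0.3 s refractory separation --
#'   event-level pedometry, robust to the window length.
#' * `"per_window"`: one step per positive window.
#' * `"per_run"`: one step per maximal positive run.
#'
#' @param detector A [train_step_detector()] model (any object whose
#'   `predict` method returns logicals over feature rows works).
#' @param stream A [sensor_stream()].
#' @param window_s Window length in seconds (default 1).
#' @param overlap_fraction Window overlap fraction in `[0, 1)` (default 0).
#' @param merge_gap_windows Merge positive runs separated by at most this
#'   many negative windows (default 0).
#' @param rule Counting rule, see above.
#' @return An object of class `step_events`: positive window start times,
#'   maximal runs (`start_s`, `end_s`), detected `step_times_s` (peaks rule)
#'   and the total `step_count`.
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(), 900, seed = 2)
#' fm <- build_feature_matrix(segment_windows(ds$stream, ds$schedule, length_s = 1))
#' if (length(unique(fm$label == "walking")) == 2) {
#'   det <- train_step_detector(fm, seed = 1)
#'   ev <- count_steps(det, ds$stream)
#'   c(identified = ev$step_count, actual = length(ds$true_step_times_s))
#' }
count_steps <- function(detector, stream, window_s = 1.0, overlap_fraction = 0,
                        merge_gap_windows = 0L,
                        rule = c("peaks", "per_window", "per_run")) {
  rule <- match.arg(rule)
  rate <- stream$sample_rate_hz
  if (round(window_s * rate) > length(stream$t_s)) {
    warning("stream shorter than one window; zero step events", call. = FALSE)
    return(structure(
      list(
        window_starts_s = numeric(0), runs = empty_runs(),
        step_times_s = numeric(0), step_count = 0L, rule = rule,
        window_s = window_s
      ),
      class = "step_events"
    ))
  }
  ws <- segment_windows(stream,
    labels = NULL, length_s = window_s,
    overlap_fraction = overlap_fraction
  )
  feats <- featurize_window_set(ws)
  positive <- as.logical(predict(detector, feats))
  pos_idx <- which(positive)
  runs <- positive_runs(pos_idx, ws, merge_gap_windows)
  step_times <- numeric(0)
  count <- switch(rule,
    per_window = length(pos_idx),
    per_run = nrow(runs),
    peaks = {
      step_times <- detect_step_peaks(stream, runs)
      length(step_times)
    }
  )
  structure(
    list(
      window_starts_s = ws$start_s[pos_idx], runs = runs,
      step_times_s = step_times, step_count = as.integer(count), rule = rule,
      window_s = window_s
    ),
    class = "step_events"
  )
}

empty_runs <- function() data.frame(start_s = numeric(0), end_s = numeric(0))

# maximal spans of consecutive positive windows, with optional gap bridging
positive_runs <- function(pos_idx, ws, merge_gap_windows = 0L) {
  if (!length(pos_idx)) {
    return(empty_runs())
  }
  gap <- diff(pos_idx)
  new_run <- c(TRUE, gap > merge_gap_windows + 1L)
  grp <- cumsum(new_run)
  first <- pos_idx[!duplicated(grp)]
  last <- pos_idx[!duplicated(grp, fromLast = TRUE)]
  data.frame(
    start_s = ws$start_s[first],
    end_s = ws$start_s[last] + ws$length_s
  )
}

# one step per dominant peak of the dynamic acceleration magnitude in a run:
# detrended |a|, minimum height half the run RMS, 0.3 s refractory distance
detect_step_peaks <- function(stream, runs) {
  if (!nrow(runs)) {
    return(numeric(0))
  }
  rate <- stream$sample_rate_hz
  acc <- stream$channels[, c("ax", "ay", "az"), drop = FALSE]
  mag <- sqrt(rowSums(acc^2))
  out <- numeric(0)
  for (r in seq_len(nrow(runs))) {
    idx <- which(stream$t_s >= runs$start_s[r] - 1e-9 &
      stream$t_s < runs$end_s[r] - 1e-9)
    if (length(idx) < 3L) next
    s <- mag[idx] - mean(mag[idx])
    rms <- sqrt(mean(s^2))
    if (rms == 0) next
    pk <- pracma::findpeaks(s,
      minpeakheight = 0.5 * rms,
      minpeakdistance = max(1L, round(0.3 * rate))
    )
    if (!is.null(pk)) out <- c(out, stream$t_s[idx[pk[, 2L]]])
  }
  sort(out)
}

#' @export
print.step_events <- function(x, ...) {
  cat(sprintf(
    "Step events: %d steps (%s rule), %d positive %g-s windows in %d runs\n",
    x$step_count, x$rule, length(x$window_starts_s), x$window_s, nrow(x$runs)
  ))
  invisible(x)
}

#' Step-count accuracy
#'
#' `100 * (1 - |identified - actual| / actual)`: 100 exactly when counts
#' agree, and symmetric in over- versus under-counting magnitude.
#'
#' @param identified Detected step count (non-negative).
#' @param actual Reference (manually counted or ground-truth) steps (> 0).
#' @return Accuracy in percent.
#' @export
#' @examples
#' step_accuracy(39 + 6 + 20, 45 + 6 + 24) # pooled over three animals
step_accuracy <- function(identified, actual) {
  if (!is_number(actual) || actual <= 0) stopf("actual step count must be > 0")
  if (!is_number(identified) || identified < 0) stopf("identified must be >= 0")
  100 * (1 - abs(identified - actual) / actual)
}

#' Aggregate per-animal step-count results over a cohort
#'
#' @param results Data frame with columns `animal_id`, `identified`,
#'   `actual` (one row per animal, all `actual > 0`).
#' @return An object of class `cohort_step_report`: the per-animal table with
#'   accuracies plus `pooled_accuracy_pct` (from summed counts) and
#'   `mean_accuracy_pct` (unweighted mean of per-animal accuracies).
#' @export
#' @examples
#' cohort_step_report(data.frame(
#'   animal_id = c("C8", "C9", "C10"),
#'   identified = c(39, 6, 20), actual = c(45, 6, 24)
#' ))
cohort_step_report <- function(results) {
  results <- as.data.frame(results)
  if (!nrow(results)) stopf("no per-animal results")
  need <- c("animal_id", "identified", "actual")
  if (!all(need %in% names(results))) {
    stopf("results must have columns: %s", paste(need, collapse = ", "))
  }
  if (any(results$actual <= 0)) stopf("all actual step counts must be > 0")
  results$accuracy_pct <- mapply(step_accuracy, results$identified, results$actual)
  structure(
    list(
      per_animal = results,
      pooled_accuracy_pct = step_accuracy(sum(results$identified), sum(results$actual)),
      mean_accuracy_pct = mean(results$accuracy_pct)
    ),
    class = "cohort_step_report"
  )
}

#' @export
print.cohort_step_report <- function(x, ...) {
  cat(sprintf("Cohort step-count report (%d animals)\n", nrow(x$per_animal)))
  df <- x$per_animal
  df$accuracy_pct <- round(df$accuracy_pct, 2)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf(
    "Pooled accuracy %.2f%% | mean per-animal accuracy %.2f%%\n",
    x$pooled_accuracy_pct, x$mean_accuracy_pct
  ))
  invisible(x)
}

#' Count ground-truth steps inside a time interval
#'
#' @param dataset A [simulate_dataset()] result.
#' @param from,to Interval bounds in seconds (defaults: whole recording).
#' @return Integer count of true step events in `[from, to)`.
#' @export
true_step_count <- function(dataset, from = 0, to = Inf) {
  sum(dataset$true_step_times_s >= from & dataset$true_step_times_s < to)
}
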