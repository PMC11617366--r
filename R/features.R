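# Windowed time-series features for behaviour classification.
#
# Per channel x of length n (population conventions, 1/n):
#   F1 mean          sum(x)/n
#   F2 variance      sum((x - F1)^2)/n
#   F3 RMS           sqrt(sum(x^2)/n)
#   F4 skewness      m3 / m2^(3/2)   (0 when m2 == 0)
#   F5 kurtosis      m4 / m2^2 - 3   (0 when m2 == 0; excess)
#   F6 energy        sum(x^2)
#   F8 IAV           sum(|x|) * dt   (integral of absolute value)

feature_codes <- function() c("F1", "F2", "F3", "F4", "F5", "F6", "F8")

#' Feature names in fixed channel-major order
#'
#' @return Character vector of length 63: `ax_F1 ... ax_F8, ay_F1, ...`.
#' @export
feature_names <- function() {
  as.vector(t(outer(imu_channel_names(), feature_codes(), paste, sep = "_")))
}

# Core feature kernel: M is an n x m matrix holding m windows of one channel
# in its columns; returns a 7 x m matrix of features.  Every public path
# (single-window extraction, bulk feature matrices, step-counter windows)
# funnels through this one function.
channel_features <- function(M, dt_s) {
  n <- nrow(M)
  f1 <- colMeans(M)
  C <- M - rep(f1, each = n)
  m2 <- colMeans(C^2)
  m3 <- colMeans(C^3)
  m4 <- colMeans(C^4)
  sq <- colSums(M^2)
  f4 <- ifelse(m2 > 0, m3 / m2^1.5, 0)
  f5 <- ifelse(m2 > 0, m4 / m2^2 - 3, 0)
  rbind(
    F1 = f1, F2 = m2, F3 = sqrt(sq / n), F4 = f4, F5 = f5,
    F6 = sq, F8 = colSums(abs(M)) * dt_s
  )
}

#' Extract the seven-feature vector from one labeled window
#'
#' @param samples Numeric matrix, one row per sample, 9 IMU channels in
#'   `ax, ay, az, gx, gy, gz, mx, my, mz` order.
#' @param dt_s Sample period in seconds (used by the integral-of-absolute-
#'   value feature so its value is sampling-rate invariant).
#' @return Named numeric vector of length 63 in [feature_names()] order.
#' @export
#' @examples
#' w <- matrix(rnorm(200 * 9), 200, 9)
#' f <- extract_features(w, dt_s = 1 / 20)
#' f[c("ax_F1", "az_F3")]
extract_features <- function(samples, dt_s) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L) stopf("a window needs at least 2 samples")
  if (ncol(samples) != 9L) stopf("expected 9 IMU channels, got %d", ncol(samples))
  vals <- as.vector(channel_features(samples, dt_s)) # feature-major per channel
  stats::setNames(vals, feature_names())
}

#' Segment a sensor stream into fixed-length labeled windows
#'
#' Tiles the stream with windows of `length_s` seconds at the configured
#' overlap.  Each window takes the behaviour label covering a strict majority
#' (> 50 percent) of its duration; windows with no strict majority (ties,
#' boundary straddles, uncovered spans) stay unlabeled (`NA`) and are
#' retained so prediction-time paths can still featurize them, but are
#' excluded from training matrices.
#'
#' @param stream A [sensor_stream()].
#' @param labels Optional label intervals: a data frame with `start_s`,
#'   `end_s`, `behavior` (a [generate_schedule()] result works directly).
#' @param length_s Window length in seconds (default 10).
#' @param overlap_fraction Fraction of overlap between consecutive windows,
#'   in `[0, 1)` (default 0).
#' @return An object of class `window_set`: the stream plus per-window start
#'   indices, start times and labels.
#' @export
#' @examples
#' cfg <- sim_config()
#' ds <- simulate_dataset(cfg, 300, seed = 1)
#' ws <- segment_windows(ds$stream, ds$schedule, length_s = 10)
#' table(ws$label, useNA = "ifany")
segment_windows <- function(stream, labels = NULL, length_s = 10,
                            overlap_fraction = 0) {
  if (!inherits(stream, "sensor_stream")) stopf("stream must be a sensor_stream")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stopf("overlap_fraction must lie in [0, 1)")
  }
  rate <- stream$sample_rate_hz
  w <- round(length_s * rate)
  if (w < 2L) stopf("window of %g s holds fewer than 2 samples at %g Hz", length_s, rate)
  n <- length(stream$t_s)
  if (w > n) {
    warning("window longer than stream; no windows produced", call. = FALSE)
    starts <- integer(0)
  } else {
    step <- max(1L, round(w * (1 - overlap_fraction)))
    starts <- seq.int(1L, n - w + 1L, by = step)
  }
  start_s <- stream$t_s[starts]
  lab <- rep(NA_character_, length(starts))
  if (!is.null(labels) && length(starts)) {
    lab <- majority_label(start_s, length_s, labels)
  }
  structure(
    list(
      stream = stream, start_idx = starts, n_samples = w,
      length_s = length_s, start_s = start_s, label = lab,
      dt_s = 1 / rate
    ),
    class = "window_set"
  )
}

# strict-majority label of each [start, start + length) window
majority_label <- function(start_s, length_s, intervals) {
  intervals <- as.data.frame(intervals)
  intervals$behavior <- as_behavior(intervals$behavior)
  nw <- length(start_s)
  labs <- unique(intervals$behavior)
  cov <- matrix(0, nw, length(labs), dimnames = list(NULL, labs))
  for (i in seq_len(nrow(intervals))) {
    ov <- pmax(
      0,
      pmin(start_s + length_s, intervals$end_s[i]) - pmax(start_s, intervals$start_s[i])
    )
    cov[, intervals$behavior[i]] <- cov[, intervals$behavior[i]] + ov
  }
  best <- max.col(cov, ties.method = "first")
  top <- cov[cbind(seq_len(nw), best)]
  out <- labs[best]
  out[top <= length_s / 2 + 1e-9] <- NA_character_ # strict majority required
  out
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf(
    "Window set: %d windows of %g s (%d samples), %d labeled\n",
    length(x$start_idx), x$length_s, x$n_samples, sum(!is.na(x$label))
  ))
  invisible(x)
}

# bulk-featurize a window_set: 63 columns, one row per window
featurize_window_set <- function(ws) {
  nw <- length(ws$start_idx)
  out <- matrix(NA_real_, nw, 63L, dimnames = list(NULL, feature_names()))
  if (nw == 0L) {
    return(out)
  }
  idx <- outer(seq_len(ws$n_samples) - 1L, ws$start_idx, "+") # n x nw
  for (ch in seq_len(9L)) {
    M <- matrix(ws$stream$channels[as.vector(idx), ch], nrow = ws$n_samples)
    out[, (ch - 1L) * 7L + seq_len(7L)] <- t(channel_features(M, ws$dt_s))
  }
  out
}

#' Build a feature matrix from labeled windows
#'
#' Featurizes every labeled window of one or more window sets, ordering rows
#' by (animal, window start time) so the result is independent of input
#' order.
#'
#' @param windows A `window_set` or a list of them (one per animal).
#' @param animal_id Animal id(s) matching `windows`; defaults to the stream's
#'   own id.
#' @param keep_unlabeled Keep unlabeled windows (label `NA`)?  Default
#'   `FALSE`; prediction-time callers set `TRUE`.
#' @return An object of class `feature_matrix`: list with `x` (numeric
#'   matrix, 63 columns), `label`, `animal_id`, `start_s`.
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(), 300, seed = 1)
#' fm <- build_feature_matrix(segment_windows(ds$stream, ds$schedule))
#' dim(fm$x)
build_feature_matrix <- function(windows, animal_id = NULL, keep_unlabeled = FALSE) {
  if (inherits(windows, "window_set")) windows <- list(windows)
  if (!length(windows)) stopf("no windows supplied")
  ids <- animal_id
  if (is.null(ids)) {
    ids <- vapply(windows, function(w) {
      id <- w$stream$animal_id
      if (is.na(id)) "A1" else id
    }, character(1))
  }
  ids <- rep_len(ids, length(windows))
  parts <- lapply(seq_along(windows), function(i) {
    ws <- windows[[i]]
    keep <- if (keep_unlabeled) seq_along(ws$start_idx) else which(!is.na(ws$label))
    if (!length(keep)) {
      return(NULL)
    }
    x <- featurize_window_set(ws)[keep, , drop = FALSE]
    list(
      x = x, label = ws$label[keep], start_s = ws$start_s[keep],
      animal_id = rep(ids[i], length(keep))
    )
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) stopf("all windows are unlabeled; nothing to featurize")
  x <- do.call(rbind, lapply(parts, `[[`, "x"))
  label <- unlist(lapply(parts, `[[`, "label"))
  start_s <- unlist(lapply(parts, `[[`, "start_s"))
  aid <- unlist(lapply(parts, `[[`, "animal_id"))
  o <- order(aid, start_s)
  structure(
    list(
      x = x[o, , drop = FALSE], label = label[o],
      animal_id = aid[o], start_s = start_s[o]
    ),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "Feature matrix: %d windows x %d features, %d animal(s)\n",
    nrow(x$x), ncol(x$x), length(unique(x$animal_id))
  ))
  if (any(!is.na(x$label))) print(table(x$label, useNA = "ifany"))
  invisible(x)
}
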