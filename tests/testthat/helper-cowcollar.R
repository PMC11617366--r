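# Shared fixtures, built in code at test time.

# single-behaviour schedule helper
one_bout <- function(behavior, duration_s) {
  as_schedule(data.frame(start_s = 0, end_s = duration_s, behavior = behavior))
}

# independent sort-based median (oracle; deliberately avoids stats::median)
oracle_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

# independent centered rolling median with symmetric shrinking edges (oracle)
oracle_rolling_median <- function(x, k) {
  n <- length(x)
  h <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)
    oracle_median(x[(i - hi):(i + hi)])
  }, numeric(1))
}

# independent linear-interpolation quantile (oracle)
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# independent brute-force loop implementation of the seven features
oracle_features <- function(x, dt) {
  n <- length(x)
  f1 <- 0
  for (v in x) f1 <- f1 + v
  f1 <- f1 / n
  m2 <- m3 <- m4 <- sq <- iav <- 0
  for (v in x) {
    d <- v - f1
    m2 <- m2 + d^2
    m3 <- m3 + d^3
    m4 <- m4 + d^4
    sq <- sq + v^2
    iav <- iav + abs(v)
  }
  m2 <- m2 / n
  m3 <- m3 / n
  m4 <- m4 / n
  c(
    F1 = f1, F2 = m2, F3 = sqrt(sq / n),
    F4 = if (m2 > 0) m3 / m2^1.5 else 0,
    F5 = if (m2 > 0) m4 / m2^2 - 3 else 0,
    F6 = sq, F8 = iav * dt
  )
}

# wrap a plain feature matrix as the package's feature_matrix container
fake_feature_matrix <- function(x, label, animal_id = "A1",
                                start_s = seq_len(nrow(x)) - 1) {
  structure(
    list(
      x = x, label = label,
      animal_id = rep_len(animal_id, nrow(x)),
      start_s = start_s
    ),
    class = "feature_matrix"
  )
}

# separable two-class feature rows for classifier sanity checks
separable_features <- function(n_per_class = 20, seed = 1) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per_class * 63, mean = 0, sd = 0.1), ncol = 63),
    matrix(rnorm(n_per_class * 63, mean = 3, sd = 0.1), ncol = 63)
  )
  colnames(x) <- feature_names()
  fake_feature_matrix(x, rep(c("walking", "grazing"), each = n_per_class))
}

# feature matrices for a simulated cohort, one window set per animal
cohort_features <- function(n_animals, duration_s, window_s,
                            config = sim_config(), base_seed = 0) {
  cohort <- generate_cohort(n_animals, config, duration_s, base_seed = base_seed)
  build_feature_matrix(lapply(cohort, function(d) {
    segment_windows(d$stream, d$schedule, length_s = window_s)
  }))
}
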