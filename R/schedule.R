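#' Generate a semi-Markov behaviour schedule
#'
#' Simulates a sequence of behaviour bouts for one animal.  Bout (dwell)
#' durations are drawn per behaviour from a gamma distribution with shape 4
#' and mean `dwell_mean_s[behavior]`, so bouts concentrate around their mean
#' rather than piling up near zero; successive behaviours are drawn from the
#' configured transition matrix.  Whenever the sampled move crosses posture
#' families (standing-family to lying rest or back), the corresponding
#' transition class is inserted for `transition_duration_s` seconds.  The last
#' bout is truncated at `duration_s`; adjacent bouts with the same label are
#' merged.
#'
#' @param config A [sim_config()].
#' @param duration_s Total schedule duration in seconds (> 0).
#' @param seed Integer seed; the schedule is bit-reproducible for a fixed seed.
#' @return A `behavior_schedule`: a data frame with columns `start_s`,
#'   `end_s`, `behavior`, and attribute `total_duration_s`.  Segments are
#'   contiguous, non-overlapping and cover `[0, duration_s)`.
#' @export
#' @examples
#' sched <- generate_schedule(sim_config(), duration_s = 600, seed = 7)
#' head(sched)
generate_schedule <- function(config, duration_s, seed = config$seed) {
  validate_sim_config(config)
  if (!is_number(duration_s) || duration_s <= 0) stopf("duration_s must be > 0")
  tm <- config$transition_matrix
  with_seed(seed + SEED_OFFSET_SCHEDULE, {
    # initial bout drawn from average inbound probability over main
    # behaviours, so degenerate matrices (e.g. one absorbing state) start in
    # the state they force
    p0 <- colSums(tm[, main_behaviors(), drop = FALSE])
    if (sum(p0) <= 0) p0 <- rep(1, length(main_behaviors()))
    state <- sample(main_behaviors(), 1L, prob = p0)
    t0 <- 0
    starts <- numeric(0)
    ends <- numeric(0)
    labs <- character(0)
    push <- function(a, b, lab) {
      starts[length(starts) + 1L] <<- a
      ends[length(ends) + 1L] <<- b
      labs[length(labs) + 1L] <<- lab
    }
    while (t0 < duration_s) {
      dwell <- if (state %in% main_behaviors()) {
        stats::rgamma(1L, shape = 4, scale = config$dwell_mean_s[[state]] / 4)
      } else {
        config$transition_duration_s
      }
      t1 <- min(t0 + dwell, duration_s)
      push(t0, t1, state)
      t0 <- t1
      if (t0 >= duration_s) break
      nxt <- sample(behavior_levels(), 1L, prob = tm[state, ])
      # bridge posture changes with the matching transition class
      if (nxt %in% main_behaviors() && posture_of(state) != posture_of(nxt)) {
        bridge <- if (posture_of(nxt) == "lying") "stand_to_lie" else "lie_to_stand"
        t1 <- min(t0 + config$transition_duration_s, duration_s)
        push(t0, t1, bridge)
        t0 <- t1
      }
      state <- nxt
    }
    seg <- data.frame(
      start_s = starts, end_s = ends, behavior = labs,
      stringsAsFactors = FALSE
    )
    seg <- merge_adjacent(seg)
    structure(seg,
      total_duration_s = duration_s,
      class = c("behavior_schedule", "data.frame")
    )
  })
}

# collapse runs of identical adjacent labels into single segments
merge_adjacent <- function(seg) {
  if (nrow(seg) < 2L) {
    return(seg)
  }
  keep <- c(TRUE, seg$behavior[-1L] != seg$behavior[-nrow(seg)])
  grp <- cumsum(keep)
  data.frame(
    start_s = tapply(seg$start_s, grp, min),
    end_s = tapply(seg$end_s, grp, max),
    behavior = seg$behavior[keep],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Build a behaviour schedule from explicit intervals
#'
#' @param segments Data frame with `start_s`, `end_s`, `behavior` (behaviour
#'   names are normalised case-insensitively); intervals must not overlap.
#' @param total_duration_s Total recording duration; defaults to the last
#'   interval end.
#' @return A `behavior_schedule`.
#' @export
#' @examples
#' as_schedule(data.frame(start_s = 0, end_s = 60, behavior = "walking"))
as_schedule <- function(segments, total_duration_s = max(segments$end_s)) {
  segments$behavior <- as_behavior(segments$behavior)
  o <- order(segments$start_s)
  segments <- segments[o, , drop = FALSE]
  if (nrow(segments) > 1L &&
    any(segments$start_s[-1L] < segments$end_s[-nrow(segments)] - 1e-9)) {
    stopf("behavior intervals overlap")
  }
  structure(segments,
    total_duration_s = total_duration_s,
    class = c("behavior_schedule", "data.frame")
  )
}

#' @export
print.behavior_schedule <- function(x, ...) {
  cat(sprintf(
    "Behavior schedule: %d segments over %.1f s\n",
    nrow(x), attr(x, "total_duration_s")
  ))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more segments\n", nrow(x) - 10L))
  invisible(x)
}

# total time each behaviour covers within [from, to)
schedule_time_by_behavior <- function(schedule, from = 0,
                                      to = attr(schedule, "total_duration_s")) {
  ov <- pmax(0, pmin(schedule$end_s, to) - pmax(schedule$start_s, from))
  tapply(ov, schedule$behavior, sum)
}
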