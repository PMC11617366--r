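#' The seven-class cattle ethogram
#'
#' Behaviour classes recognised throughout the package, in canonical order:
#' `feeding`, `grazing`, `walking`, `lying_resting`, `standing_resting`, and
#' the two posture transitions `stand_to_lie` and `lie_to_stand`.  Labels are
#' serialised as lowercase snake-case text.
#'
#' @return Character vector of the seven behaviour labels.
#' @export
#' @examples
#' behavior_levels()
behavior_levels <- function() {
  c(
    "feeding", "grazing", "walking", "lying_resting", "standing_resting",
    "stand_to_lie", "lie_to_stand"
  )
}

# Main (dwellable) behaviours; transitions are inserted mechanically between
# posture families and are never dwelt in beyond their fixed duration.
main_behaviors <- function() {
  c("feeding", "grazing", "walking", "lying_resting", "standing_resting")
}

# Posture family of each behaviour ("standing" or "lying"); transitions carry
# the family they end in so that interpolation end points are well defined.
posture_of <- function(label) {
  lying <- c("lying_resting", "stand_to_lie")
  ifelse(label %in% lying, "lying", "standing")
}

#' Normalise behaviour labels
#'
#' Maps free-text behaviour names (any case, spaces or hyphens in place of
#' underscores) onto the canonical seven-class ethogram.
#'
#' @param x Character vector of behaviour names.
#' @return Character vector of canonical labels.
#' @export
#' @examples
#' as_behavior(c("Grazing", "LYING RESTING"))
as_behavior <- function(x) {
  norm <- tolower(gsub("[ -]+", "_", trimws(as.character(x))))
  bad <- !norm %in% behavior_levels()
  if (any(bad)) {
    stopf(
      "unknown behavior label(s): %s; valid labels are: %s",
      paste(unique(x[bad]), collapse = ", "),
      paste(behavior_levels(), collapse = ", ")
    )
  }
  norm
}

# Factor with the canonical level order restricted to levels present.
behavior_factor <- function(x) {
  x <- as_behavior(x)
  factor(x, levels = behavior_levels()[behavior_levels() %in% unique(x)])
}
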