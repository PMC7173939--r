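#' Discrete action states
#'
#' The seven mutually exclusive per-frame action labels used throughout the
#' pipeline, in the canonical order used for tie-breaking and for the rows
#' and columns of transition matrices: Crawl, Bend, Stop, Hunch, Backup,
#' Roll, Small. `NoAction` is a transient label that can exist between the
#' first-layer detectors and the second classification layer; it never
#' appears in a final ethogram.
#'
#' @return Character vector of the seven action names.
#' @export
action_states <- function() {
  c("Crawl", "Bend", "Stop", "Hunch", "Backup", "Roll", "Small")
}

#' Postural states
#'
#' Static shape classes of the contour, regularized sequentially in the
#' order Ball, Curl, Bend, StraightLightBend, Straight (the light-bend class
#' exists to support back-up detection).
#'
#' @return Character vector of posture names in regularization order.
#' @export
posture_states <- function() {
  c("Ball", "Curl", "Bend", "StraightLightBend", "Straight")
}

action_factor <- function(x) {
  factor(as.character(x), levels = action_states())
}

stopifnot_actions <- function(x) {
  bad <- setdiff(unique(as.character(x)), c(action_states(), "NoAction"))
  if (length(bad) > 0L) {
    stop("unknown action state(s): ", paste(bad, collapse = ", "))
  }
  invisible(x)
}
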