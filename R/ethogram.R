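#' Per-larva ethogram
#'
#' A timeline of mutually exclusive discrete action states, one per frame,
#' plus its event segmentation (maximal constant-state runs). Frame
#' indices are 0-based and events are half-open `[start, end)`.
#'
#' @param track_id Identifier.
#' @param times Frame times (s).
#' @param actions Character/factor vector of per-frame actions.
#' @param events Optional precomputed event table.
#' @return Object of class `ethogram`.
#' @export
ethogram <- function(track_id, times, actions, events = NULL) {
  actions <- as.character(actions)
  stopifnot(length(times) == length(actions))
  stopifnot_actions(actions)
  if (is.null(events)) events <- segment_events(actions, times)
  structure(list(track_id = as.character(track_id), times = as.numeric(times),
                 actions = actions, events = events),
            class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("<ethogram %s: %d frames, %d events>\n", x$track_id,
              length(x$times), nrow(x$events)))
  invisible(x)
}

#' A collection of ethograms with a common stimulus clock
#'
#' @param line_id Genotype label.
#' @param ethograms List of [ethogram()]s.
#' @param stimulus A [stimulus_schedule()].
#' @return Object of class `ethogram_set`.
#' @export
ethogram_set <- function(line_id, ethograms, stimulus = stimulus_schedule()) {
  stopifnot(all(vapply(ethograms, inherits, logical(1), "ethogram")))
  structure(list(line_id = as.character(line_id), ethograms = ethograms,
                 stimulus = stimulus),
            class = "ethogram_set")
}

#' @export
print.ethogram_set <- function(x, ...) {
  cat(sprintf("<ethogram_set %s: %d larvae>\n", x$line_id, length(x$ethograms)))
  invisible(x)
}

#' Segment a per-frame state sequence into events
#'
#' Maximal constant-state runs, with amplitude summaries (min/max/mean
#' length, minimal S, mean center speed) when a feature table is supplied.
#'
#' @param states Per-frame action states.
#' @param times Frame times (s).
#' @param ftab Optional feature table aligned with `states`.
#' @return Data frame with columns `action`, `start`, `end` (0-based,
#'   half-open), `t_start`, `t_end`, `duration`, `n_frames`, and amplitude
#'   columns if `ftab` given.
#' @export
segment_events <- function(states, times, ftab = NULL) {
  states <- as.character(states)
  n <- length(states)
  if (n == 0L) {
    return(data.frame(action = character(0), start = integer(0), end = integer(0),
                      t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0), n_frames = integer(0)))
  }
  r <- rle(states)
  end1 <- cumsum(r$lengths)        # 1-based inclusive
  start1 <- end1 - r$lengths + 1L
  dt_last <- if (n > 1L) times[n] - times[n - 1L] else 0
  t_end <- ifelse(end1 < n, times[pmin(end1 + 1L, n)], times[n] + dt_last)
  ev <- data.frame(action = r$values, start = start1 - 1L, end = end1,
                   t_start = times[start1], t_end = t_end,
                   duration = t_end - times[start1], n_frames = r$lengths,
                   stringsAsFactors = FALSE)
  if (!is.null(ftab)) {
    amp <- t(vapply(seq_len(nrow(ev)), function(i) {
      idx <- (ev$start[i] + 1L):ev$end[i]
      c(l_min = min(ftab$l[idx], na.rm = TRUE),
        l_max = max(ftab$l[idx], na.rm = TRUE),
        l_mean = mean(ftab$l[idx], na.rm = TRUE),
        lM_min = min(ftab$l_M[idx], na.rm = TRUE),
        lM_max = max(ftab$l_M[idx], na.rm = TRUE),
        S_min = suppressWarnings(min(ftab$S[idx], na.rm = TRUE)),
        v_mean = mean(ftab$v_center[idx], na.rm = TRUE))
    }, numeric(7)))
    ev <- cbind(ev, as.data.frame(amp))
  }
  ev
}

#' Render an ethogram set as a tidy table
#'
#' @param es An `ethogram_set`.
#' @return Data frame (track, frame, time, action); the per-frame states
#'   are fully reconstructible from it.
#' @export
ethogram_table <- function(es) {
  do.call(rbind, lapply(es$ethograms, function(e) {
    data.frame(track_id = e$track_id, frame = seq_along(e$times) - 1L,
               time = e$times, action = e$actions, stringsAsFactors = FALSE)
  }))
}

#' Plot an ethogram set as action-colored larva rows
#'
#' @param x An `ethogram_set`.
#' @param ... Unused.
#' @export
plot.ethogram_set <- function(x, ...) {
  cols <- c(Crawl = "black", Bend = "red", Stop = "green3", Hunch = "blue",
            Backup = "cyan3", Roll = "orange", Small = "grey60")
  n <- length(x$ethograms)
  tr <- range(unlist(lapply(x$ethograms, function(e) range(e$times))))
  graphics::plot(NA, xlim = tr, ylim = c(0, n + 1), xlab = "time (s)",
                 ylab = "larva", yaxt = "n", main = x$line_id)
  for (i in seq_len(n)) {
    ev <- x$ethograms[[i]]$events
    graphics::rect(ev$t_start, i - 0.4, ev$t_end, i + 0.4,
                   col = cols[ev$action], border = NA)
  }
  graphics::abline(v = x$stimulus$onset, col = "magenta", lwd = 2)
  invisible(x)
}
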