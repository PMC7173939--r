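action_at_time <- function(e, t) {
  # action of one ethogram at clock time t, NA if not tracked there
  if (t < e$times[1L] || t > e$times[length(e$times)]) return(NA_character_)
  e$actions[findInterval(t, e$times)]
}

#' Behavior probability time series
#'
#' For each half-open window of duration `2 * dt` (default dt = 0.1 s),
#' the fraction of active larvae performing each action:
#' `P_a = (# larvae in a) / (# active larvae)`. A larva is active in a
#' window if it is tracked at the window midpoint; windows with no active
#' larva have undefined (NA) probabilities.
#'
#' @param es An `ethogram_set`.
#' @param dt Half-window (s); windows have width `2 * dt`.
#' @param t_range Optional time range (defaults to the union of tracks).
#' @return List of class `probability_timeseries`: `time` (window
#'   midpoints), `P` (windows x 7 matrix), `n_active`.
#' @export
behavior_probability_timeseries <- function(es, dt = 0.1, t_range = NULL) {
  if (is.null(t_range)) {
    t_range <- range(unlist(lapply(es$ethograms, function(e) range(e$times))))
  }
  w <- 2 * dt
  starts <- seq(t_range[1L], t_range[2L], by = w)
  mids <- starts + dt
  acts <- action_states()
  nw <- length(mids)
  counts <- matrix(0L, nw, 7L, dimnames = list(NULL, acts))
  n_active <- integer(nw)
  for (e in es$ethograms) {
    valid <- mids >= e$times[1L] & mids <= e$times[length(e$times)]
    if (!any(valid)) next
    idx <- findInterval(mids[valid], e$times)
    ai <- match(e$actions[idx], acts)
    wv <- which(valid)
    n_active[wv] <- n_active[wv] + 1L
    counts[cbind(wv, ai)] <- counts[cbind(wv, ai)] + 1L
  }
  P <- counts / ifelse(n_active > 0L, n_active, NA_real_)
  structure(list(time = mids, P = P, n_active = n_active, window = w),
            class = "probability_timeseries")
}

#' Dominant and second dominant behavior per window
#'
#' @param pts A `probability_timeseries`.
#' @return Data frame (time, dominant, second); ties broken by the fixed
#'   action order Crawl, Bend, Stop, Hunch, Backup, Roll, Small.
#' @export
dominant_behaviors <- function(pts) {
  acts <- colnames(pts$P)
  res <- t(apply(pts$P, 1L, function(p) {
    if (all(is.na(p))) return(c(NA_character_, NA_character_))
    o <- order(-p) # stable: ties keep canonical column order
    acts[o[1:2]]
  }))
  data.frame(time = pts$time, dominant = res[, 1L], second = res[, 2L],
             stringsAsFactors = FALSE)
}

window_frames <- function(e, t0, t1) {
  which(e$times >= t0 & e$times < t1)
}

#' Per-action probabilities over fixed windows
#'
#' Mode `"fraction-of-time"`: the mean over larvae of the within-window
#' fraction of time spent in each action. Mode `"ever"` delegates to
#' [cumulative_counts()]. Windows (default 1, 5, 15 s) are evaluated from
#' the stimulus onset and from its offset; larvae not tracked during the
#' whole window are excluded.
#'
#' @param es An `ethogram_set`.
#' @param stimulus A [stimulus_schedule()] (defaults to the set's).
#' @param windows Window lengths (s).
#' @param mode `"fraction-of-time"` or `"ever"`.
#' @return Data frame: reference (onset/offset), window, action, value,
#'   n_larvae.
#' @export
window_probabilities <- function(es, stimulus = es$stimulus,
                                 windows = c(1, 5, 15),
                                 mode = c("fraction-of-time", "ever")) {
  mode <- match.arg(mode)
  if (mode == "ever") {
    cc <- cumulative_counts(es, stimulus, windows)
    cc$value <- cc$fraction
    return(cc)
  }
  refs <- c(onset = stimulus$onset, offset = stimulus$onset + stimulus$duration)
  acts <- action_states()
  out <- list()
  for (rn in names(refs)) for (w in windows) {
    t0 <- refs[[rn]]; t1 <- t0 + w
    fr <- matrix(0, 0L, 7L)
    for (e in es$ethograms) {
      if (e$times[1L] > t0 || e$times[length(e$times)] < t1) next
      i <- window_frames(e, t0, t1)
      if (!length(i)) next
      dtf <- diff(c(e$times[i], min(t1, e$times[min(length(e$times), max(i) + 1L)])))
      dtf[dtf < 0] <- 0
      tf <- vapply(acts, function(a) sum(dtf[e$actions[i] == a]), numeric(1))
      fr <- rbind(fr, tf / sum(tf))
    }
    for (a in seq_along(acts)) {
      out[[length(out) + 1L]] <- data.frame(
        reference = rn, window = w, action = acts[a],
        value = if (nrow(fr)) mean(fr[, a]) else NA_real_,
        n_larvae = nrow(fr), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' At-least-once action counts over fixed windows
#'
#' Counts larvae performing each action at least once in each window after
#' stimulus onset and offset.
#'
#' @inheritParams window_probabilities
#' @return Data frame: reference, window, action, count, n_larvae,
#'   fraction.
#' @export
cumulative_counts <- function(es, stimulus = es$stimulus, windows = c(1, 5, 15)) {
  refs <- c(onset = stimulus$onset, offset = stimulus$onset + stimulus$duration)
  acts <- action_states()
  out <- list()
  for (rn in names(refs)) for (w in windows) {
    t0 <- refs[[rn]]; t1 <- t0 + w
    counts <- stats::setNames(numeric(7L), acts)
    n <- 0L
    for (e in es$ethograms) {
      if (e$times[1L] > t0 || e$times[length(e$times)] < t1) next
      i <- window_frames(e, t0, t1)
      if (!length(i)) next
      n <- n + 1L
      seen <- unique(e$actions[i])
      counts[seen] <- counts[seen] + 1L
    }
    for (a in acts) {
      out[[length(out) + 1L]] <- data.frame(
        reference = rn, window = w, action = a, count = counts[[a]],
        n_larvae = n, fraction = if (n) counts[[a]] / n else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Transition matrix over a time window
#'
#' Counts ordered event adjacencies whose transition instant falls inside
#' the half-open window (default: the first 3 s after stimulus onset),
#' pooled over larvae; rows are normalized to probabilities. The diagonal
#' is structurally zero; rows with no transitions are all-NA after
#' normalization.
#'
#' @param es An `ethogram_set`.
#' @param window Numeric `c(t0, t1)`; default `onset + c(0, 3)`.
#' @return List of class `transition_matrix`: `counts` (7 x 7 integer),
#'   `probabilities`, `window`.
#' @export
transition_matrix <- function(es, window = NULL) {
  if (is.null(window)) window <- es$stimulus$onset + c(0, 3)
  acts <- action_states()
  N <- matrix(0L, 7L, 7L, dimnames = list(acts, acts))
  for (e in es$ethograms) {
    ev <- e$events
    if (nrow(ev) < 2L) next
    for (i in seq_len(nrow(ev) - 1L)) {
      tswitch <- ev$t_end[i]
      if (tswitch >= window[1L] && tswitch < window[2L]) {
        N[ev$action[i], ev$action[i + 1L]] <- N[ev$action[i], ev$action[i + 1L]] + 1L
      }
    }
  }
  rs <- rowSums(N)
  P <- N / ifelse(rs > 0, rs, NA_real_)
  structure(list(counts = N, probabilities = P, window = window),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix over [%g, %g) s; %d transitions>\n",
              x$window[1L], x$window[2L], sum(x$counts)))
  print(round(x$probabilities, 3))
  invisible(x)
}

#' First post-stimulus action sequences
#'
#' The first (up to) four actions performed after stimulus onset. The
#' action ongoing at onset counts as the first response only if it
#' persists at least `dt_blur` beyond onset (the perception-uncertainty
#' window); otherwise the first new post-onset action opens the
#' sequence. Crawl is a legal sequence element.
#'
#' @param es An `ethogram_set`.
#' @param stimulus A [stimulus_schedule()].
#' @param dt_blur Perception uncertainty (s).
#' @param max_actions Sequence length cap.
#' @return Data frame: track_id, position, action, ambiguous (whether the
#'   dt_blur rule decided the first element).
#' @export
extract_sequences <- function(es, stimulus = es$stimulus, dt_blur = 0.5,
                              max_actions = 4L) {
  onset <- stimulus$onset
  out <- list()
  for (e in es$ethograms) {
    if (e$times[1L] > onset || e$times[length(e$times)] < onset) next
    ev <- e$events
    cur <- which(ev$t_start <= onset & ev$t_end > onset)
    if (!length(cur)) next
    persists <- ev$t_end[cur] - onset >= dt_blur
    first_idx <- if (persists) cur else cur + 1L
    if (first_idx > nrow(ev)) next
    idx <- first_idx:min(nrow(ev), first_idx + max_actions - 1L)
    # consecutive events always differ in action, so the list is the
    # sequence of different actions performed
    out[[length(out) + 1L]] <- data.frame(
      track_id = e$track_id, position = seq_along(idx),
      action = ev$action[idx], ambiguous = !persists,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(track_id = character(0), position = integer(0),
                      action = character(0), ambiguous = logical(0)))
  }
  do.call(rbind, out)
}

#' Hunch- and bend-amplitude statistics
#'
#' Per Hunch event the relative length variation
#' `delta(l) = (l_max - l_min) / l_max` and ratio `r(l) = l_min / l_max`
#' (both for `l` and `l_M`); per Bend event the minimal S.
#'
#' @param events Event table with amplitude summaries (possibly pooled).
#' @return List with `hunch` (delta_l, r_l, delta_lM, r_lM per event) and
#'   `bend` (S_min per event; their mean is the population amplitude).
#' @export
amplitude_stats <- function(events) {
  h <- events[events$action == "Hunch", , drop = FALSE]
  b <- events[events$action == "Bend", , drop = FALSE]
  list(
    hunch = data.frame(
      delta_l = (h$l_max - h$l_min) / h$l_max,
      r_l = h$l_min / h$l_max,
      delta_lM = (h$lM_max - h$lM_min) / h$lM_max,
      r_lM = h$lM_min / h$lM_max),
    bend = data.frame(S_min = b$S_min),
    bend_mean_min_S = if (nrow(b)) mean(b$S_min) else NA_real_)
}

wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  ifelse(y == -pi, pi, y)
}

#' Larva orientation at stimulus onset versus first response
#'
#' For each larva, the angle `theta = theta_e1 - theta_w` between its
#' head segment (neck-up to head) and the wind direction
#' (`theta_w = 3 pi / 2`) at stimulus onset, wrapped to `(-pi, pi]`,
#' together with its first post-onset action; empirical CDFs per
#' first-action group and pairwise two-sample Kolmogorov-Smirnov tests.
#'
#' @param ts A `track_set` of oriented tracks.
#' @param es The matching `ethogram_set`.
#' @param stimulus A [stimulus_schedule()].
#' @param theta_w Wind direction (rad).
#' @return List with `records` (track_id, theta, first_action), `cdfs`
#'   (per-action ecdf functions), and `ks` (pairwise D and p; groups with
#'   fewer than 2 larvae skipped).
#' @export
orientation_analysis <- function(ts, es, stimulus = es$stimulus,
                                 theta_w = 3 * pi / 2) {
  seqs <- extract_sequences(es, stimulus)
  first <- seqs[seqs$position == 1L, c("track_id", "action")]
  onset <- stimulus$onset
  recs <- list()
  for (tr in ts$tracks) {
    fa <- first$action[match(tr$track_id, first$track_id)]
    if (is.na(fa) || onset < tr$times[1L] || onset > tr$times[length(tr$times)]) next
    i <- findInterval(onset, tr$times)
    nux <- (tr$spine_x[i, 8L] + tr$spine_x[i, 9L]) / 2
    nuy <- (tr$spine_y[i, 8L] + tr$spine_y[i, 9L]) / 2
    th <- atan2(tr$spine_y[i, 11L] - nuy, tr$spine_x[i, 11L] - nux)
    recs[[length(recs) + 1L]] <- data.frame(
      track_id = tr$track_id, theta = wrap_angle(th - theta_w),
      first_action = fa, stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(track_id = character(0), theta = numeric(0),
               first_action = character(0))
  groups <- split(records$theta, records$first_action)
  cdfs <- lapply(groups, stats::ecdf)
  gg <- names(groups)[vapply(groups, length, integer(1)) >= 2L]
  ks <- list()
  if (length(gg) >= 2L) {
    for (i in seq_len(length(gg) - 1L)) for (j in (i + 1L):length(gg)) {
      kt <- suppressWarnings(stats::ks.test(groups[[gg[i]]], groups[[gg[j]]]))
      ks[[length(ks) + 1L]] <- data.frame(
        action1 = gg[i], action2 = gg[j],
        D = unname(kt$statistic), p = kt$p.value, stringsAsFactors = FALSE)
    }
  }
  list(records = records, cdfs = cdfs,
       ks = if (length(ks)) do.call(rbind, ks) else NULL)
}
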