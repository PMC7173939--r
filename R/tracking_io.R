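#' Construct a larva track
#'
#' The raw unit of analysis: one tracked animal's timestamped 11-point spine
#' and closed-contour series. Spines are stored as two `T x 11` coordinate
#' matrices; the oriented convention is tail = spine point 1, head = spine
#' point 11 (tracker output may arrive with arbitrary, frame-varying
#' endpoint order until [orient_track()] has been applied). Contours are a
#' list of `n x 2` closed polygons (first point not repeated).
#'
#' @param track_id Identifier.
#' @param times Strictly increasing frame times (seconds).
#' @param spine_x,spine_y `T x 11` matrices of spine coordinates (mm).
#' @param contours List of `T` two-column matrices (mm), or `NULL`.
#' @param pixel_scale mm per coordinate unit (already-applied scale is 1).
#' @return An object of class `larva_track`.
#' @export
larva_track <- function(track_id, times, spine_x, spine_y, contours = NULL,
                        pixel_scale = 1) {
  times <- as.numeric(times)
  spine_x <- as.matrix(spine_x)
  spine_y <- as.matrix(spine_y)
  if (ncol(spine_x) != 11L || ncol(spine_y) != 11L) {
    stop("spines must have exactly 11 points per frame")
  }
  if (nrow(spine_x) != length(times) || nrow(spine_y) != length(times)) {
    stop("spine matrices and times disagree in length")
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  if (!is.null(contours)) {
    if (length(contours) != length(times)) {
      stop("contours and times disagree in length")
    }
    nc <- vapply(contours, nrow, integer(1))
    if (any(nc < 3L)) stop("every contour needs at least 3 points")
  }
  structure(
    list(track_id = as.character(track_id), times = times,
         spine_x = spine_x, spine_y = spine_y, contours = contours,
         pixel_scale = pixel_scale),
    class = "larva_track")
}

#' @export
print.larva_track <- function(x, ...) {
  cat(sprintf("<larva_track %s: %d frames, %.1f-%.1f s%s>\n",
              x$track_id, length(x$times),
              if (length(x$times)) min(x$times) else NA_real_,
              if (length(x$times)) max(x$times) else NA_real_,
              if (is.null(x$contours)) ", no contours" else ""))
  invisible(x)
}

n_frames <- function(track) length(track$times)

#' Per-frame true body length
#'
#' Sum of the ten spine-segment norms, `l = sum_i ||r_s(i+1) - r_s(i)||`.
#'
#' @param track A `larva_track`.
#' @return Numeric vector of lengths (mm).
#' @export
track_length <- function(track) {
  dx <- track$spine_x[, -1L, drop = FALSE] - track$spine_x[, -11L, drop = FALSE]
  dy <- track$spine_y[, -1L, drop = FALSE] - track$spine_y[, -11L, drop = FALSE]
  rowSums(sqrt(dx^2 + dy^2))
}

track_com <- function(track) {
  if (!is.null(track$contours)) {
    xy <- vapply(track$contours, colMeans, numeric(2))
    cbind(x = xy[1L, ], y = xy[2L, ])
  } else {
    cbind(x = rowMeans(track$spine_x), y = rowMeans(track$spine_y))
  }
}

subset_track <- function(track, idx) {
  larva_track(track$track_id, track$times[idx],
              track$spine_x[idx, , drop = FALSE],
              track$spine_y[idx, , drop = FALSE],
              if (is.null(track$contours)) NULL else track$contours[idx],
              track$pixel_scale)
}

#' Stimulus schedule
#'
#' The air-puff protocol: a main stimulus (default onset 45 s, duration
#' 38 s) optionally followed by a train of short pulses.
#'
#' @param onset Main stimulus onset (s).
#' @param duration Main stimulus duration (s).
#' @param pulse_train Optional two-column matrix / data.frame of
#'   (onset, duration) for later pulses; onsets must be increasing and
#'   non-overlapping.
#' @return An object of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(onset = 45, duration = 38, pulse_train = NULL) {
  if (!is.null(pulse_train)) {
    pulse_train <- as.data.frame(pulse_train)
    names(pulse_train) <- c("onset", "duration")
    ends <- c(onset + duration, utils::head(pulse_train$onset + pulse_train$duration, -1L))
    if (any(pulse_train$onset < ends)) stop("stimulus pulses must be increasing and non-overlapping")
  }
  structure(list(onset = onset, duration = duration, pulse_train = pulse_train),
            class = "stimulus_schedule")
}

#' Construct a track set
#'
#' A per-genotype collection of larva tracks with its stimulus schedule.
#'
#' @param line_id Genotype label.
#' @param tracks List of `larva_track`s.
#' @param stimulus A [stimulus_schedule()].
#' @return An object of class `track_set`.
#' @export
track_set <- function(line_id, tracks, stimulus = stimulus_schedule()) {
  stopifnot(all(vapply(tracks, inherits, logical(1), "larva_track")))
  names(tracks) <- vapply(tracks, `[[`, character(1), "track_id")
  structure(list(line_id = as.character(line_id), tracks = tracks,
                 stimulus = stimulus),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set %s: %d tracks, stimulus onset %g s>\n",
              x$line_id, length(x$tracks), x$stimulus$onset))
  invisible(x)
}

# ---- native dialect -------------------------------------------------------

#' Write a track set in the native delimited dialect
#'
#' One text file per track set. Header lines start with `#` and carry
#' line id, pixel scale and stimulus schedule. Each data row is
#' whitespace-delimited: `track_id time x1 y1 ... x11 y11 n_contour
#' cx1 cy1 ... cxn cyn`.
#'
#' @param ts A `track_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  st <- ts$stimulus
  writeLines(c(
    sprintf("# line_id %s", ts$line_id),
    sprintf("# pixel_scale %.17g", ts$tracks[[1L]]$pixel_scale %||% 1),
    sprintf("# stimulus %.17g %.17g", st$onset, st$duration)), con)
  if (!is.null(st$pulse_train)) {
    writeLines(sprintf("# pulse %.17g %.17g", st$pulse_train$onset,
                       st$pulse_train$duration), con)
  }
  for (tr in ts$tracks) {
    for (i in seq_along(tr$times)) {
      sp <- as.vector(rbind(tr$spine_x[i, ], tr$spine_y[i, ]))
      if (is.null(tr$contours)) {
        cc <- numeric(0); nc <- 0L
      } else {
        cm <- tr$contours[[i]]
        cc <- as.vector(t(cm)); nc <- nrow(cm)
      }
      writeLines(paste(c(tr$track_id, sprintf("%.10g", tr$times[i]),
                         sprintf("%.10g", sp), nc, sprintf("%.10g", cc)),
                       collapse = " "), con)
    }
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a track set from the native dialect or ground-truth sidecar
#'
#' Malformed frames (wrong coordinate count, spine not 11 points) are
#' dropped with a warning carrying the dropped-frame count.
#'
#' @param path File written by [write_tracks()].
#' @return A `track_set` with a `dropped_frames` attribute.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("cannot read tracks: no such file: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_hdr <- function(key) {
    m <- hdr[startsWith(hdr, paste0("# ", key))]
    if (!length(m)) return(NULL)
    strsplit(sub(paste0("# ", key, " "), "", m[1L]), " ", fixed = TRUE)[[1L]]
  }
  line_id <- get_hdr("line_id") %||% "unknown"
  pixel_scale <- as.numeric(get_hdr("pixel_scale") %||% "1")
  stim_raw <- as.numeric(get_hdr("stimulus") %||% c("45", "38"))
  pulses <- hdr[startsWith(hdr, "# pulse ")]
  pulse_train <- NULL
  if (length(pulses)) {
    pm <- do.call(rbind, lapply(strsplit(sub("# pulse ", "", pulses), " "), as.numeric))
    pulse_train <- data.frame(onset = pm[, 1L], duration = pm[, 2L])
  }
  toks <- strsplit(body, "[[:space:]]+")
  dropped <- 0L
  rows <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) < 25L) { dropped <- dropped + 1L; next }
    nc <- suppressWarnings(as.integer(tk[25L]))
    if (is.na(nc) || length(tk) != 25L + 2L * nc) { dropped <- dropped + 1L; next }
    vals <- suppressWarnings(as.numeric(tk[-1L]))
    if (anyNA(vals)) { dropped <- dropped + 1L; next }
    rows[[i]] <- list(id = tk[1L], time = vals[1L],
                      spine = vals[2L:23L],
                      contour = if (nc > 0L) matrix(vals[24L + seq_len(2L * nc)],
                                                    ncol = 2L, byrow = TRUE))
  }
  if (dropped > 0L) warning(sprintf("dropped %d malformed frame(s)", dropped))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  ids <- vapply(rows, `[[`, character(1), "id")
  tracks <- lapply(split(seq_along(rows), factor(ids, levels = unique(ids))), function(ii) {
    tt <- vapply(rows[ii], `[[`, numeric(1), "time")
    o <- order(tt)
    ii <- ii[o]; tt <- tt[o]
    sp <- t(vapply(rows[ii], `[[`, numeric(22L), "spine"))
    contours <- lapply(rows[ii], `[[`, "contour")
    if (any(vapply(contours, is.null, logical(1)))) contours <- NULL
    larva_track(rows[[ii[1L]]]$id, tt,
                sp[, seq(1L, 21L, by = 2L), drop = FALSE],
                sp[, seq(2L, 22L, by = 2L), drop = FALSE],
                contours, pixel_scale)
  })
  ts <- track_set(line_id, unname(tracks),
                  stimulus_schedule(stim_raw[1L], stim_raw[2L], pulse_train))
  attr(ts, "dropped_frames") <- dropped
  ts
}

#' Write / read a ground-truth sidecar table
#'
#' Tab-delimited table with columns track_id, frame, time, action,
#' true_head_end, accompanying a synthetic track set.
#'
#' @param truth Data frame as produced by [simulate_population()].
#' @param path File path.
#' @return `path` (write) or the data frame (read).
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

# ---- cleaning -------------------------------------------------------------

#' Clean a single track
#'
#' Applies the screen's track hygiene: removes the first 5 and last 10
#' frames (tracker edge anomalies), then rejects the track if (a) it spans
#' less than `min_seconds`, (b) its net center-of-mass displacement is less
#' than one mean body length, (c) fewer than `min_frames` frames remain, or
#' (d) the convex hull of the center-of-mass trajectory has area below
#' `min_hull_mm2`.
#'
#' @param track A `larva_track`.
#' @param min_seconds,min_frames,min_hull_mm2 Rejection thresholds.
#' @param trim_head,trim_tail Frames removed at the ends.
#' @return List with `disposition` ("kept" or "rejected"), `reason`,
#'   `frames_removed`, and `track` (trimmed, or `NULL` if rejected).
#' @export
clean_track <- function(track, min_seconds = 5, min_frames = 250,
                        min_hull_mm2 = 1, trim_head = 5, trim_tail = 10) {
  nf <- n_frames(track)
  if (isTRUE(attr(track, "edge_trimmed"))) {
    # cleaning is idempotent: edge frames are removed only once
    tr <- track
    idx <- seq_len(nf)
  } else {
    if (nf <= trim_head + trim_tail) {
      return(list(disposition = "rejected", reason = "min-frames",
                  frames_removed = nf, track = NULL))
    }
    idx <- (trim_head + 1L):(nf - trim_tail)
    tr <- subset_track(track, idx)
    attr(tr, "edge_trimmed") <- TRUE
  }
  reject <- function(reason) list(disposition = "rejected", reason = reason,
                                  frames_removed = nf - length(idx), track = NULL)
  if (diff(range(tr$times)) < min_seconds) return(reject("min-duration"))
  com <- track_com(tr)
  net <- sqrt(sum((com[nrow(com), ] - com[1L, ])^2))
  if (net < mean(track_length(tr))) return(reject("min-displacement"))
  if (length(tr$times) < min_frames) return(reject("min-frames"))
  hull <- grDevices::chull(com)
  hx <- com[hull, 1L]; hy <- com[hull, 2L]
  area <- abs(sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)) / 2
  if (area < min_hull_mm2) return(reject("hull-area"))
  list(disposition = "kept", reason = NA_character_,
       frames_removed = nf - length(idx), track = tr)
}

#' Clean every track of a set
#'
#' @param ts A `track_set`.
#' @param ... Passed to [clean_track()].
#' @return List with the cleaned `track_set` and a `report` data frame
#'   (one row per input track: track_id, disposition, reason,
#'   frames_removed).
#' @export
clean_tracks <- function(ts, ...) {
  res <- lapply(ts$tracks, clean_track, ...)
  report <- data.frame(
    track_id = vapply(ts$tracks, `[[`, character(1), "track_id"),
    disposition = vapply(res, `[[`, character(1), "disposition"),
    reason = vapply(res, `[[`, character(1), "reason"),
    frames_removed = vapply(res, function(r) as.integer(r$frames_removed), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  kept <- Filter(Negate(is.null), lapply(res, `[[`, "track"))
  out <- ts
  out$tracks <- kept
  names(out$tracks) <- vapply(kept, `[[`, character(1), "track_id")
  list(track_set = out, report = report)
}

# ---- timebase -------------------------------------------------------------

interp_rows <- function(M, times, grid) {
  i <- findInterval(grid, times, all.inside = TRUE)
  f <- (grid - times[i]) / (times[i + 1L] - times[i])
  f <- pmin(1, pmax(0, f))
  M[i, , drop = FALSE] * (1 - f) + M[i + 1L, , drop = FALSE] * f
}

#' Frame-interval statistics and uniform-grid resample
#'
#' Reports the per-track dt summary and produces a linear-interpolation
#' copy of the track on a uniform grid at the track's median dt, the grid
#' on which convolution-based kinematic features are computed.
#'
#' @param track A `larva_track` with at least two frames.
#' @return List with `stats` (mean, sd, min, max, median of dt) and
#'   `resampled` (a `larva_track` on the uniform grid).
#' @export
validate_timebase <- function(track) {
  if (n_frames(track) < 2L) stop("need at least 2 frames")
  dts <- diff(track$times)
  if (any(dts <= 0)) stop("times must be strictly increasing")
  dt_med <- stats::median(dts)
  grid <- seq(track$times[1L], track$times[n_frames(track)], by = dt_med)
  sx <- interp_rows(track$spine_x, track$times, grid)
  sy <- interp_rows(track$spine_y, track$times, grid)
  contours <- NULL
  if (!is.null(track$contours)) {
    nc <- vapply(track$contours, nrow, integer(1))
    if (length(unique(nc)) == 1L) {
      CX <- t(vapply(track$contours, function(m) m[, 1L], numeric(nc[1L])))
      CY <- t(vapply(track$contours, function(m) m[, 2L], numeric(nc[1L])))
      gx <- interp_rows(CX, track$times, grid)
      gy <- interp_rows(CY, track$times, grid)
      contours <- lapply(seq_along(grid), function(i) cbind(gx[i, ], gy[i, ]))
    } else {
      # ragged contours cannot be interpolated pointwise: take nearest frame
      ni <- vapply(grid, function(g) which.min(abs(track$times - g)), integer(1))
      contours <- track$contours[ni]
    }
  }
  list(stats = c(mean = mean(dts), sd = stats::sd(dts), min = min(dts),
                 max = max(dts), median = dt_med),
       resampled = larva_track(track$track_id, grid, sx, sy, contours,
                               track$pixel_scale))
}
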