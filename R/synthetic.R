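#' Default per-action kinetic parameters
#'
#' Mean event durations follow the free-locomotion statistics (crawl runs
#' of ~10 s, bends of ~1 s, with occasional stops and back-ups); the
#' remaining amplitudes are free parameters of the generator chosen to make
#' the classes kinematically separable: displacement speeds in body lengths
#' per second, bend amplitude as the head-axis deviation in radians, hunch
#' shortening as the relative length loss (beyond the peristaltic
#' amplitude), and the peristaltic oscillation of crawling.
#'
#' @return Named list of per-action parameter blocks.
#' @export
default_action_kinetics <- function() {
  list(
    Crawl  = list(mean_duration = 10, mean_duration_post = 3, speed = 0.15,
                  peristalsis_amplitude = 0.08, peristalsis_period = 1.0),
    Bend   = list(mean_duration = 1.2, mean_duration_post = 1.2,
                  bend_amplitude = 1.6),
    Stop   = list(mean_duration = 1.5, mean_duration_post = 1.5),
    Hunch  = list(mean_duration = 1.0, mean_duration_post = 1.0,
                  shortening = 0.3),
    Backup = list(mean_duration = 1.5, mean_duration_post = 1.5, speed = 0.08),
    Roll   = list(mean_duration = 1.0, mean_duration_post = 1.0),
    Small  = list(mean_duration = 1.0, mean_duration_post = 1.0,
                  amplitude_scale = 0.25))
}

default_transition_pre <- function() {
  a <- action_states()
  P <- matrix(0, 7, 7, dimnames = list(a, a))
  P["Crawl", c("Bend", "Stop", "Hunch", "Backup")] <- c(0.74, 0.18, 0.02, 0.06)
  P["Bend", c("Crawl", "Stop", "Hunch", "Backup")] <- c(0.90, 0.06, 0.01, 0.03)
  P["Stop", c("Crawl", "Bend", "Hunch", "Backup")] <- c(0.70, 0.28, 0.01, 0.01)
  P["Hunch", c("Crawl", "Bend", "Stop")] <- c(0.50, 0.40, 0.10)
  P["Backup", c("Crawl", "Bend", "Stop")] <- c(0.60, 0.35, 0.05)
  P["Roll", c("Crawl", "Bend")] <- c(0.5, 0.5)
  P["Small", c("Crawl", "Bend")] <- c(0.5, 0.5)
  P
}

default_transition_post <- function() {
  a <- action_states()
  P <- matrix(0, 7, 7, dimnames = list(a, a))
  P["Crawl", c("Bend", "Stop", "Hunch", "Backup")] <- c(0.70, 0.15, 0.05, 0.10)
  P["Bend", c("Crawl", "Stop", "Hunch", "Backup", "Small")] <- c(0.55, 0.20, 0.10, 0.10, 0.05)
  P["Stop", c("Crawl", "Bend", "Hunch", "Backup", "Small")] <- c(0.40, 0.40, 0.10, 0.05, 0.05)
  P["Hunch", c("Crawl", "Bend", "Stop", "Backup", "Small")] <- c(0.25, 0.45, 0.15, 0.10, 0.05)
  P["Backup", c("Crawl", "Bend", "Stop", "Hunch", "Small")] <- c(0.35, 0.40, 0.15, 0.05, 0.05)
  P["Roll", c("Crawl", "Bend")] <- c(0.5, 0.5)
  P["Small", c("Crawl", "Bend", "Stop", "Hunch", "Backup")] <- c(0.35, 0.35, 0.15, 0.10, 0.05)
  P
}

default_post_initial <- function() {
  c(Crawl = 0.08, Bend = 0.35, Stop = 0.12, Hunch = 0.30, Backup = 0.10,
    Roll = 0, Small = 0.05)
}

validate_transition_matrix <- function(P, name = "transition matrix") {
  if (!is.matrix(P) || any(dim(P) != 7L)) stop(name, " must be 7x7")
  if (any(abs(diag(P)) > 0)) stop(name, " must have zero diagonal")
  if (any(P < 0)) stop(name, " must be non-negative")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-12)) stop(name, " rows must sum to 1 within 1e-12")
  invisible(P)
}

#' Synthetic-population configuration
#'
#' Defines the study conditions emulated by the generator: tracker frame
#' jitter (mean 0.082 s, sd 0.013 s, floor 0.028 s), the air-puff schedule
#' (onset 45 s, 38 s duration), the pre- and post-stimulus action
#' transition matrices with the post-onset initial-action distribution, the
#' per-action kinetics, contour sampling (point count drawn per track from
#' Normal(114, 23), clipped at 40), and the endpoint-order corruption
#' model. Positions are in mm and time in seconds; the default larva is
#' 4 mm long.
#'
#' @param n_larvae Number of larvae.
#' @param duration Track duration (s).
#' @param dt_mean,dt_sd,dt_min Frame-interval truncated-normal jitter (s).
#' @param stimulus A [stimulus_schedule()].
#' @param action_kinetics See [default_action_kinetics()].
#' @param transition_pre,transition_post 7x7 row-stochastic zero-diagonal
#'   event-transition matrices (rows/cols in [action_states()] order).
#' @param post_initial Distribution of the first post-onset action.
#' @param flip_persistence Probability that a frame keeps the previous
#'   stored endpoint order (orientation corruption); flips in the MWT are
#'   rare discrete events, hence the high default.
#' @param body_length Resting larva length (mm).
#' @param body_width Maximal contour half-width (mm).
#' @param contour_mean,contour_sd,contour_min Contour point count model.
#' @param noise_mm Tracker positional jitter on spine points (mm).
#' @param heading_diffusion Heading random-walk scale (rad per sqrt s).
#' @param pixel_scale mm per coordinate unit.
#' @param seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_larvae = 50, duration = 80,
                             dt_mean = 0.082, dt_sd = 0.013, dt_min = 0.028,
                             stimulus = stimulus_schedule(),
                             action_kinetics = default_action_kinetics(),
                             transition_pre = default_transition_pre(),
                             transition_post = default_transition_post(),
                             post_initial = default_post_initial(),
                             flip_persistence = 0.999,
                             body_length = 4, body_width = 0.4,
                             contour_mean = 114, contour_sd = 23,
                             contour_min = 40,
                             noise_mm = 0.005, heading_diffusion = 0.25,
                             pixel_scale = 1, seed = 1L) {
  stopifnot(dt_mean > 0, flip_persistence >= 0, flip_persistence <= 1,
            duration > 0, body_length > 0)
  validate_transition_matrix(transition_pre, "transition_pre")
  validate_transition_matrix(transition_post, "transition_post")
  if (abs(sum(post_initial) - 1) > 1e-12) stop("post_initial must sum to 1")
  structure(list(
    n_larvae = n_larvae, duration = duration, dt_mean = dt_mean,
    dt_sd = dt_sd, dt_min = dt_min, stimulus = stimulus,
    action_kinetics = action_kinetics, transition_pre = transition_pre,
    transition_post = transition_post, post_initial = post_initial,
    flip_persistence = flip_persistence, body_length = body_length,
    body_width = body_width, contour_mean = contour_mean,
    contour_sd = contour_sd, contour_min = contour_min, noise_mm = noise_mm,
    heading_diffusion = heading_diffusion, pixel_scale = pixel_scale,
    seed = as.integer(seed)), class = "synthetic_config")
}

jump_stationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- pmax(v / sum(v), 0)
  v / sum(v)
}

#' Time-occupancy distribution implied by a configuration
#'
#' For the semi-Markov action process, the long-run fraction of time in
#' each state is the jump-chain stationary distribution weighted by the
#' mean dwell times.
#'
#' @param cfg A `synthetic_config`.
#' @param phase `"pre"` or `"post"` stimulus.
#' @return Named probability vector over [action_states()].
#' @export
configured_occupancy <- function(cfg, phase = c("pre", "post")) {
  phase <- match.arg(phase)
  P <- if (phase == "pre") cfg$transition_pre else cfg$transition_post
  nu <- jump_stationary(P)
  dur_field <- if (phase == "pre") "mean_duration" else "mean_duration_post"
  tau <- vapply(action_states(), function(a) cfg$action_kinetics[[a]][[dur_field]],
                numeric(1))
  occ <- nu * tau
  stats::setNames(occ / sum(occ), action_states())
}

# ---- action plan ----------------------------------------------------------

draw_duration <- function(mean_dur, min_dur) {
  max(min_dur, stats::rexp(1L, rate = 1 / mean_dur))
}

sample_next <- function(P, from) {
  p <- P[from, ]
  if (sum(p) <= 0) stop("degenerate transition row for state ", from)
  sample.int(7L, 1L, prob = p)
}

#' Sample a semi-Markov action plan
#'
#' Event sequence covering `cfg$duration`: exponential dwell times with the
#' configured per-action means, jump transitions from the pre-stimulus
#' matrix before the stimulus onset and from the post-stimulus matrix
#' after. At onset the ongoing action is interrupted and the first
#' post-onset action is drawn from `cfg$post_initial` (the stimulus
#' response). Identical seeds reproduce identical plans.
#'
#' @param cfg A `synthetic_config`.
#' @param seed Integer seed.
#' @return A data frame of class `action_plan` with columns `action`,
#'   `duration`, `t_start`.
#' @export
sample_action_sequence <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  a <- action_states()
  min_dur <- 3 * cfg$dt_mean
  onset <- cfg$stimulus$onset
  nu <- jump_stationary(cfg$transition_pre)
  reachable_pre <- which(nu > 1e-12)
  if (any(rowSums(cfg$transition_pre[reachable_pre, , drop = FALSE]) <= 0)) {
    stop("degenerate pre-stimulus transition matrix")
  }
  tau <- vapply(a, function(x) cfg$action_kinetics[[x]]$mean_duration, numeric(1))
  occ <- nu * tau / sum(nu * tau)
  state <- sample.int(7L, 1L, prob = occ)
  t <- 0
  acts <- integer(0); durs <- numeric(0); starts <- numeric(0)
  push <- function(s, d) {
    n <- length(acts)
    if (n > 0L && acts[n] == s) { # merge equal neighbours
      durs[n] <<- durs[n] + d
    } else {
      acts <<- c(acts, s); durs <<- c(durs, d); starts <<- c(starts, t)
    }
  }
  phase_end <- min(onset, cfg$duration)
  while (t < phase_end - 1e-12) {
    d <- min(draw_duration(cfg$action_kinetics[[a[state]]]$mean_duration, min_dur),
             phase_end - t)
    push(state, d)
    t <- t + d
    if (t < phase_end - 1e-12) state <- sample_next(cfg$transition_pre, state)
  }
  if (cfg$duration > onset) {
    state <- sample.int(7L, 1L, prob = cfg$post_initial)
    while (t < cfg$duration - 1e-12) {
      d <- min(draw_duration(cfg$action_kinetics[[a[state]]]$mean_duration_post,
                             min_dur),
               cfg$duration - t)
      push(state, d)
      t <- t + d
      if (t < cfg$duration - 1e-12) state <- sample_next(cfg$transition_post, state)
    }
  }
  plan <- data.frame(action = a[acts], duration = durs, t_start = starts,
                     stringsAsFactors = FALSE)
  class(plan) <- c("action_plan", "data.frame")
  plan
}

# ---- track generation -----------------------------------------------------

smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

# fraction of the head-axis deviation carried by each of the ten segments:
# the posterior third stays on the body axis, the curvature builds toward
# the head as in a head cast
bend_weights <- c(0, 0, 0, 0.05, 0.15, 0.30, 0.50, 0.70, 0.88, 1.0)

#' Generate a tracker-realistic track from an action plan
#'
#' Builds an 11-point spine per frame from a midline model (heading, length
#' modulation, anterior bend profile) and a closed contour by offsetting
#' the midline with a tapered width profile whose head end is sharper than
#' its tail end. Crawl moves the center of mass parallel to the tail-to-
#' head axis with peristaltic length oscillation; Backup moves it
#' antiparallel; Hunch shortens the body by the configured relative amount
#' (beyond the peristaltic amplitude) and recovers; Bend deviates the head
#' axis; Stop freezes the midline; Small replays Bend or Hunch at
#' sub-threshold amplitude. Frame times carry the configured truncated-
#' normal jitter. The emitted spine is tail-first (head = point 11), which
#' the ground truth records as `true_head_end = "last"`.
#'
#' @param plan An `action_plan` covering the configured duration.
#' @param cfg A `synthetic_config`.
#' @param seed Integer seed.
#' @param track_id Identifier for the emitted track.
#' @return List with `track` (a `larva_track`) and `truth` (data frame
#'   with 0-based `frame`, `time`, `action`, `true_head_end`).
#' @export
generate_track <- function(plan, cfg, seed = cfg$seed, track_id = "L001") {
  set.seed(seed)
  total <- sum(plan$duration)
  n_est <- ceiling(total / cfg$dt_min) + 10L
  dts <- pmax(cfg$dt_min, stats::rnorm(n_est, cfg$dt_mean, cfg$dt_sd))
  tt <- cumsum(c(0, dts))
  tt <- tt[tt < total - 1e-9]
  Tn <- length(tt)
  ev <- findInterval(tt, plan$t_start, rightmost.closed = FALSE)
  act <- plan$action[ev]
  ph <- (tt - plan$t_start[ev]) / plan$duration[ev]
  tin <- tt - plan$t_start[ev]
  L <- cfg$body_length
  kin <- cfg$action_kinetics
  # per-event attributes
  n_ev <- nrow(plan)
  side <- sample(c(-1, 1), n_ev, replace = TRUE)
  small_is_hunch <- stats::runif(n_ev) < 0.5
  # length profile
  l <- rep(L, Tn)
  amp <- kin$Crawl$peristalsis_amplitude
  per <- kin$Crawl$peristalsis_period
  for (mode in c("Crawl", "Backup")) {
    i <- which(act == mode)
    if (length(i)) l[i] <- L * (1 - amp * (1 - cos(2 * pi * tin[i] / per)) / 2)
  }
  hunch_profile <- function(p, h) {
    depth <- ifelse(p < 0.4, smoothstep(p / 0.4),
                    ifelse(p < 0.7, 1, smoothstep((1 - p) / 0.3)))
    1 - h * depth
  }
  i <- which(act == "Hunch")
  if (length(i)) l[i] <- L * hunch_profile(ph[i], kin$Hunch$shortening)
  i <- which(act == "Small" & small_is_hunch[ev])
  if (length(i)) l[i] <- L * hunch_profile(ph[i], kin$Hunch$shortening *
                                             kin$Small$amplitude_scale)
  # bend profile (head-axis deviation, rad)
  b <- numeric(Tn)
  i <- which(act == "Bend")
  if (length(i)) b[i] <- side[ev[i]] * kin$Bend$bend_amplitude * sin(pi * ph[i])
  i <- which(act == "Small" & !small_is_hunch[ev])
  if (length(i)) b[i] <- side[ev[i]] * kin$Bend$bend_amplitude *
    kin$Small$amplitude_scale * sin(pi * ph[i])
  i <- which(act == "Crawl")
  if (length(i)) b[i] <- 0.05 * sin(2 * pi * tin[i] / per)
  # heading: slow random walk while displacing, plus the turn left by a bend
  dphi <- numeric(Tn)
  disp <- act %in% c("Crawl", "Backup")
  dts_f <- diff(c(0, tt))
  dphi[disp] <- cfg$heading_diffusion * sqrt(dts_f[disp]) * stats::rnorm(sum(disp))
  bend_ends <- which(plan$action %in% c("Bend"))
  for (e in bend_ends) {
    j <- which(ev == e)
    if (length(j)) dphi[max(j)] <- dphi[max(j)] + 0.6 * side[e] * kin$Bend$bend_amplitude
  }
  phi <- cumsum(dphi) + stats::runif(1L, 0, 2 * pi)
  # center-of-mass speed (signed along the heading)
  s <- numeric(Tn)
  i <- which(act == "Crawl")
  if (length(i)) s[i] <- kin$Crawl$speed * L * (1 - cos(2 * pi * tin[i] / per))
  i <- which(act == "Backup")
  if (length(i)) s[i] <- -kin$Backup$speed * L * (1 - cos(2 * pi * tin[i] / per))
  com <- cbind(cumsum(s * dts_f * cos(phi)), cumsum(s * dts_f * sin(phi)))
  # spine from segment angles
  psi <- outer(phi, rep(1, 10)) + outer(b, bend_weights)
  seg <- l / 10
  dxs <- seg * cos(psi); dys <- seg * sin(psi)
  UT <- upper.tri(matrix(0, 10, 10), diag = TRUE) * 1
  SX <- cbind(0, dxs %*% UT); SY <- cbind(0, dys %*% UT)
  SX <- SX - rowMeans(SX) + com[, 1L]
  SY <- SY - rowMeans(SY) + com[, 2L]
  # contour by midline offset with a tapered, head-sharper width profile
  n_c <- max(cfg$contour_min, round(stats::rnorm(1L, cfg$contour_mean, cfg$contour_sd)))
  m_side <- max(8L, (n_c - 2L) %/% 2L)
  u <- seq_len(m_side) / (m_side + 1)
  wprof <- u^0.5 * (1 - u)^0.65
  wprof <- cfg$body_width * wprof / max(wprof)
  j0 <- pmin(10L, floor(u * 10) + 1L)
  frac <- u * 10 - (j0 - 1L)
  Aint <- matrix(0, m_side, 11L)
  for (k in seq_len(m_side)) {
    Aint[k, j0[k]] <- 1 - frac[k]
    Aint[k, j0[k] + 1L] <- Aint[k, j0[k] + 1L] + frac[k]
  }
  Mx <- SX %*% t(Aint); My <- SY %*% t(Aint)
  # tangent angle interpolated continuously along the midline (a piecewise-
  # constant tangent would kink the inner offset of deep bends)
  j1 <- pmin(10L, j0 + 1L)
  Fm <- matrix(frac, nrow = Tn, ncol = m_side, byrow = TRUE)
  psi_u <- psi[, j0, drop = FALSE] * (1 - Fm) + psi[, j1, drop = FALSE] * Fm
  Nx <- -sin(psi_u); Ny <- cos(psi_u)
  W <- matrix(wprof, nrow = Tn, ncol = m_side, byrow = TRUE)
  CXr <- Mx - Nx * W; CYr <- My - Ny * W
  CXl <- Mx + Nx * W; CYl <- My + Ny * W
  rev_i <- rev(seq_len(m_side))
  CX <- cbind(SX[, 1L], CXr, SX[, 11L], CXl[, rev_i, drop = FALSE])
  CY <- cbind(SY[, 1L], CYr, SY[, 11L], CYl[, rev_i, drop = FALSE])
  # tracker noise on the spine
  SX <- SX + stats::rnorm(Tn * 11L, 0, cfg$noise_mm)
  SY <- SY + stats::rnorm(Tn * 11L, 0, cfg$noise_mm)
  contours <- lapply(seq_len(Tn), function(i) cbind(CX[i, ], CY[i, ]))
  track <- larva_track(track_id, tt, SX, SY, contours, cfg$pixel_scale)
  truth <- data.frame(track_id = track_id, frame = seq_len(Tn) - 1L, time = tt,
                      action = act, true_head_end = "last",
                      stringsAsFactors = FALSE)
  list(track = track, truth = truth)
}

#' Corrupt the stored endpoint order of a track
#'
#' Emulates tracker head-tail ambiguity: per frame, the stored spine (and
#' contour) point order is kept or reversed by a two-state Markov process
#' with stay-probability `flip_persistence`, starting unflipped. The
#' ground truth's `true_head_end` column is updated accordingly so decoded
#' orientations can be scored.
#'
#' @param track A `larva_track`.
#' @param truth Ground-truth data frame from [generate_track()].
#' @param flip_persistence Stay probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with the corrupted `track` and updated `truth` (plus a
#'   logical `flipped` column).
#' @export
corrupt_orientation <- function(track, truth, flip_persistence, seed = 1L) {
  stopifnot(flip_persistence >= 0, flip_persistence <= 1)
  set.seed(seed)
  Tn <- n_frames(track)
  stay <- stats::runif(Tn) < flip_persistence
  flipped <- logical(Tn)
  state <- FALSE
  for (i in seq_len(Tn)) {
    if (i > 1L && !stay[i]) state <- !state
    flipped[i] <- state
  }
  if (any(flipped)) {
    idx <- which(flipped)
    track$spine_x[idx, ] <- track$spine_x[idx, 11:1, drop = FALSE]
    track$spine_y[idx, ] <- track$spine_y[idx, 11:1, drop = FALSE]
    # the contour start index is moved to the other tip; the traversal
    # winding (a property of the tracker, not of head identity) is kept
    if (!is.null(track$contours)) {
      track$contours[idx] <- mapply(function(m, px, py) {
        k <- which.min((m[, 1L] - px)^2 + (m[, 2L] - py)^2)
        if (k > 1L) m[c(k:nrow(m), 1:(k - 1L)), , drop = FALSE] else m
      }, track$contours[idx], track$spine_x[idx, 1L], track$spine_y[idx, 1L],
      SIMPLIFY = FALSE)
    }
  }
  truth$true_head_end <- ifelse(flipped,
                                ifelse(truth$true_head_end == "last", "first", "last"),
                                truth$true_head_end)
  truth$flipped <- flipped
  list(track = track, truth = truth)
}

#' Simulate a labeled population
#'
#' Draws one action plan and one corrupted track per larva. The combined
#' ground truth doubles as the sidecar table of the native dialect.
#'
#' @param cfg A `synthetic_config`.
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return List with `track_set`, `truth` (combined data frame), and
#'   `plans`.
#' @export
simulate_population <- function(cfg, seed = cfg$seed) {
  tracks <- vector("list", cfg$n_larvae)
  truths <- vector("list", cfg$n_larvae)
  plans <- vector("list", cfg$n_larvae)
  for (i in seq_len(cfg$n_larvae)) {
    si <- (as.numeric(seed) * 10007 + i * 3 + 1) %% 2147483647
    id <- sprintf("L%04d", i)
    plan <- sample_action_sequence(cfg, seed = si)
    g <- generate_track(plan, cfg, seed = si + 1, track_id = id)
    g <- corrupt_orientation(g$track, g$truth, cfg$flip_persistence, seed = si + 2)
    tracks[[i]] <- g$track
    truths[[i]] <- g$truth
    plans[[i]] <- plan
  }
  list(track_set = track_set("synthetic", tracks, cfg$stimulus),
       truth = do.call(rbind, truths), plans = plans)
}

#' Simulate a population at ethogram level
#'
#' Draws action plans only and renders them as ethograms on a uniform
#' `cfg$dt_mean` clock, bypassing the geometric model. This is the input
#' of choice for screen-scale statistical simulations, where only the
#' labels matter.
#'
#' @param cfg A `synthetic_config`.
#' @param seed Integer seed.
#' @return An `ethogram_set`.
#' @export
simulate_ethograms <- function(cfg, seed = cfg$seed) {
  ethos <- vector("list", cfg$n_larvae)
  for (i in seq_len(cfg$n_larvae)) {
    si <- (as.numeric(seed) * 10007 + i * 3 + 1) %% 2147483647
    plan <- sample_action_sequence(cfg, seed = si)
    tt <- seq(0, sum(plan$duration) - cfg$dt_mean / 2, by = cfg$dt_mean)
    ev <- findInterval(tt, plan$t_start)
    # events derived from the plan itself (frame-quantized)
    r <- rle(ev)
    end1 <- cumsum(r$lengths)
    start1 <- end1 - r$lengths + 1L
    t_end <- c(tt[start1[-1L]], tt[length(tt)] + cfg$dt_mean)
    events <- data.frame(action = plan$action[r$values], start = start1 - 1L,
                         end = end1, t_start = tt[start1], t_end = t_end,
                         duration = t_end - tt[start1], n_frames = r$lengths,
                         stringsAsFactors = FALSE)
    ethos[[i]] <- ethogram(sprintf("L%04d", i), tt, plan$action[ev],
                           events = events)
  }
  ethogram_set("synthetic", ethos, cfg$stimulus)
}
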