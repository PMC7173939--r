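#' Head-tail HMM parameters
#'
#' Weights of the five energy terms (contour-curvature contrast, two
#' displacement terms, endpoint agitation, center velocity), the inverse
#' temperature, the initial state distribution and the orientation
#' stay-probability. Defaults are the values used at screen scale.
#'
#' @param alpha Five weights `(alpha_c, alpha_d1, alpha_d2, alpha_a,
#'   alpha_V)`.
#' @param beta Inverse temperature of the emission likelihood.
#' @param p_init Initial distribution over the four transition states.
#' @param stay_prob Per-step probability of keeping the orientation.
#' @param strict_ev If `TRUE`, the velocity energy uses the literal
#'   unsigned center speed; default uses the signed axial center velocity
#'   (speed projected on the stored first-to-last body axis), which carries
#'   head-direction information.
#' @return List of class `hmm_params`.
#' @export
hmm_params <- function(alpha = c(1, 0.2, 1, 0.5, 0.5), beta = 0.01,
                       p_init = rep(1 / 4, 4), stay_prob = 0.9,
                       strict_ev = FALSE) {
  stopifnot(length(alpha) == 5, stay_prob > 0, stay_prob < 1,
            abs(sum(p_init) - 1) < 1e-12)
  structure(list(alpha = alpha, beta = beta, p_init = p_init,
                 stay_prob = stay_prob, strict_ev = strict_ev),
            class = "hmm_params")
}

#' Per-frame, per-orientation emission energies
#'
#' For orientation `o` (+1: head is the stored *first* spine point, -1:
#' head is the stored *last* point) at frame `i`,
#' `E(i, o) = o * (alpha_c * dkappa + alpha_d1 * beta_10_10 +
#' alpha_a * a + alpha_V * e_v)`, where each channel is an oriented
#' evidence scalar that is positive when the stored *last* endpoint
#' behaves like the head: `dkappa = tanh(kappa_S(last) - kappa_S(first))`
#' (the head end of the smoothed contour is sharper), `beta_10_10` (the
#' larva mostly moves toward its head), `a` the endpoint agitation
#' asymmetry (the head casts more), and `e_v` the velocity evidence. The
#' displacement-consistency term `alpha_d2 * D` lives on the step level
#' and is handled inside [viterbi_orient()]. The per-frame likelihood
#' weight is proportional to `exp(-beta * E)`.
#'
#' @param ftab Feature table with channels `delta_kappa`, `beta_sym_10_10`,
#'   `endpoint_asym`, `axial_v`, `v_center`.
#' @param params An [hmm_params()].
#' @return Matrix `T x 2` of energies, columns `first`, `last`.
#' @export
emission_energies <- function(ftab, params = hmm_params()) {
  need <- c("beta_sym_10_10", "endpoint_asym", "axial_v", "v_center")
  miss <- setdiff(need, names(ftab))
  if (length(miss)) stop("missing feature channels: ", paste(miss, collapse = ", "))
  a <- params$alpha
  dk <- ftab$delta_kappa
  if (is.null(dk) || all(is.na(dk))) dk <- rep(0, nrow(ftab))
  dk[is.na(dk)] <- 0
  # stored-order channels are oriented head=last positive; dkappa as
  # computed by compute_geometry is kappa(first) - kappa(last), so negate.
  # The direction term uses the flip-antisymmetrized 10/10 alignment.
  ev_last <- a[1L] * (-dk) + a[2L] * ftab$beta_sym_10_10 +
    a[4L] * ftab$endpoint_asym +
    a[5L] * (if (params$strict_ev) ftab$v_center else ftab$axial_v)
  ev_last[is.na(ev_last)] <- 0
  E <- cbind(first = ev_last, last = -ev_last)
  E
}

step_displacement_energy <- function(track, ftab) {
  # D(i; o_i, o_i+1): body-length-normalized displacement of the inferred
  # head and tail endpoints across the step, for equal (no flip) and
  # crossed (flip) endpoint assignments
  Tn <- n_frames(track)
  p1x <- track$spine_x[, 1L]; p1y <- track$spine_y[, 1L]
  p2x <- track$spine_x[, 11L]; p2y <- track$spine_y[, 11L]
  l <- ftab$l
  i <- seq_len(Tn - 1L)
  same <- (sqrt((p1x[i + 1L] - p1x[i])^2 + (p1y[i + 1L] - p1y[i])^2) +
           sqrt((p2x[i + 1L] - p2x[i])^2 + (p2y[i + 1L] - p2y[i])^2)) / l[i]
  cross <- (sqrt((p2x[i + 1L] - p1x[i])^2 + (p2y[i + 1L] - p1y[i])^2) +
            sqrt((p1x[i + 1L] - p2x[i])^2 + (p1y[i + 1L] - p2y[i])^2)) / l[i]
  cbind(same = same, cross = cross)
}

#' Viterbi decoding of head-tail orientation
#'
#' Maximum-a-posteriori orientation sequence of the two-orientation-state
#' chain (stay probability `stay_prob`, flip `1 - stay_prob`) with
#' emission weights `exp(-beta * E)` and the step displacement-consistency
#' energy `alpha_d2 * D` added to the step score. Ties prefer no flip,
#' then head = first. Each decoded step induces one of the four printed
#' transition states (T1: 1->1, T2: 1->11, T3: 11->11, T4: 11->1 for the
#' head).
#'
#' @param energies `T x 2` emission energy matrix (columns first/last).
#' @param params An [hmm_params()].
#' @param step_D Optional `(T-1) x 2` matrix (columns same/cross) of
#'   displacement energies from the track; 0 if omitted.
#' @return List of class `orientation_path`: `head_end` (character),
#'   `transition_state` (T1..T4 per step), `logscore`,
#'   `low_confidence`.
#' @export
viterbi_orient <- function(energies, params = hmm_params(), step_D = NULL) {
  Tn <- nrow(energies)
  b <- params$beta
  em <- -b * energies # log emission weights, columns (first, last)
  if (Tn == 1L) {
    o <- if (em[1L, 1L] >= em[1L, 2L]) "first" else "last"
    return(structure(list(head_end = o, transition_state = character(0),
                          logscore = em[1L, which(c("first", "last") == o)],
                          low_confidence = TRUE),
                     class = "orientation_path"))
  }
  if (is.null(step_D)) step_D <- matrix(0, Tn - 1L, 2L,
                                        dimnames = list(NULL, c("same", "cross")))
  a_d2 <- params$alpha[3L]
  lstay <- log(params$stay_prob)
  lflip <- log1p(-params$stay_prob)
  # p_init is uniform over the four transition states, hence uniform over
  # the initial orientation; it drops out of the argmax
  V <- matrix(-Inf, Tn, 2L)
  back <- matrix(1L, Tn, 2L)
  V[1L, ] <- em[1L, ]
  for (i in 2L:Tn) {
    dsame <- -b * a_d2 * step_D[i - 1L, "same"]
    dcross <- -b * a_d2 * step_D[i - 1L, "cross"]
    for (o in 1:2) {
      cand <- c(V[i - 1L, o] + lstay + dsame,
                V[i - 1L, 3L - o] + lflip + dcross)
      # ties prefer no flip; at the state level prefer head = first
      pick <- if (cand[2L] > cand[1L]) 2L else 1L
      V[i, o] <- cand[pick] + em[i, o]
      back[i, o] <- if (pick == 1L) o else 3L - o
    }
  }
  path <- integer(Tn)
  path[Tn] <- if (V[Tn, 2L] > V[Tn, 1L]) 2L else 1L
  for (i in (Tn - 1L):1L) path[i] <- back[i + 1L, path[i + 1L]]
  head_end <- c("first", "last")[path]
  trans <- character(Tn - 1L)
  for (i in seq_len(Tn - 1L)) {
    trans[i] <- if (path[i] == 1L && path[i + 1L] == 1L) "T1"
      else if (path[i] == 1L && path[i + 1L] == 2L) "T2"
      else if (path[i] == 2L && path[i + 1L] == 2L) "T3"
      else "T4"
  }
  structure(list(head_end = head_end, transition_state = trans,
                 logscore = max(V[Tn, ]), low_confidence = FALSE),
            class = "orientation_path")
}

#' Apply a decoded orientation path to a track
#'
#' Reverses the stored spine (and contour) order on frames whose decoded
#' head is the first point, so the oriented track is tail-first (head =
#' spine point 11) everywhere.
#'
#' @param track A `larva_track`.
#' @param path An `orientation_path` (or character vector of
#'   "first"/"last") covering the track.
#' @return The oriented `larva_track`.
#' @export
apply_orientation <- function(track, path) {
  head_end <- if (inherits(path, "orientation_path")) path$head_end else path
  if (length(head_end) != n_frames(track)) stop("path length mismatch")
  idx <- which(head_end == "first")
  if (length(idx)) {
    track$spine_x[idx, ] <- track$spine_x[idx, 11:1, drop = FALSE]
    track$spine_y[idx, ] <- track$spine_y[idx, 11:1, drop = FALSE]
    # rotate the contour start to the new first spine point, keeping the
    # traversal winding
    if (!is.null(track$contours)) {
      track$contours[idx] <- mapply(function(m, px, py) {
        k <- which.min((m[, 1L] - px)^2 + (m[, 2L] - py)^2)
        if (k > 1L) m[c(k:nrow(m), 1:(k - 1L)), , drop = FALSE] else m
      }, track$contours[idx], track$spine_x[idx, 1L], track$spine_y[idx, 1L],
      SIMPLIFY = FALSE)
    }
  }
  track
}

#' Decode and apply head-tail orientation in one call
#'
#' Computes features needed by the emission model, decodes the Viterbi
#' orientation path, and returns the oriented track together with the
#' path. Orientation-dependent features must be recomputed on the
#' oriented track.
#'
#' @param track A `larva_track`.
#' @param params An [hmm_params()].
#' @param cfg A [feature_config()].
#' @param ftab Optional precomputed feature table for `track`.
#' @return List with `track` (oriented) and `path`.
#' @export
orient_track <- function(track, params = hmm_params(), cfg = feature_config(),
                         ftab = NULL) {
  if (is.null(ftab)) ftab <- compute_features(track, cfg, derive = FALSE)
  E <- emission_energies(ftab, params)
  D <- if (n_frames(track) > 1L) step_displacement_energy(track, ftab) else NULL
  path <- viterbi_orient(E, params, D)
  list(track = apply_orientation(track, path), path = path)
}

#' Strict-literal four-transition-state decoding
#'
#' Decodes the printed four-state chain (states T1..T4 over frame pairs)
#' with its block-diagonal transition matrix, for comparison with the
#' default orientation-consistent two-state model. Because the printed
#' block structure permits orientation-inconsistent chaining, the decoded
#' per-frame head assignment is taken from the departure orientation of
#' each step.
#'
#' @param energies `T x 2` emission matrix as in [viterbi_orient()].
#' @param params An [hmm_params()].
#' @return Character vector of per-frame head ends.
#' @export
viterbi_orient_4state <- function(energies, params = hmm_params()) {
  Tn <- nrow(energies)
  if (Tn < 2L) return(rep("first", Tn))
  b <- params$beta
  # state energies: T1 (1->1), T2 (1->11), T3 (11->11), T4 (11->1); the
  # departure/arrival orientations weight the two frame energies
  dep <- c(1L, 1L, 2L, 2L) # orientation index at frame i  (1 = first)
  arr <- c(1L, 2L, 2L, 1L) # orientation index at frame i+1
  A <- matrix(c(0.9, 0.1, 0, 0, 0.1, 0.9, 0, 0, 0, 0, 0.9, 0.1, 0, 0, 0.1, 0.9),
              4L, 4L, byrow = TRUE)
  lA <- log(A); lA[A == 0] <- -Inf
  n_steps <- Tn - 1L
  V <- matrix(-Inf, n_steps, 4L)
  back <- matrix(1L, n_steps, 4L)
  em <- function(i, s) -b * (energies[i, dep[s]] + energies[i + 1L, arr[s]]) / 2
  for (s in 1:4) V[1L, s] <- log(params$p_init[s]) + em(1L, s)
  if (n_steps > 1L) {
    for (i in 2L:n_steps) {
      for (s in 1:4) {
        cand <- V[i - 1L, ] + lA[, s]
        back[i, s] <- which.max(cand)
        V[i, s] <- cand[back[i, s]] + em(i, s)
      }
    }
  }
  sp <- integer(n_steps)
  sp[n_steps] <- which.max(V[n_steps, ])
  if (n_steps > 1L) for (i in (n_steps - 1L):1L) sp[i] <- back[i + 1L, sp[i + 1L]]
  c(c("first", "last")[dep[sp]], c("first", "last")[arr[sp[n_steps]]])
}
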