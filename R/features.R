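#' Feature-extraction configuration
#'
#' @param alpha_v Agitation-velocity scale (10 for the screen analysis).
#' @param fourier_order Truncation order of the contour Fourier smoothing.
#' @param deriv_window Derivative-of-Gaussian window (frames) for velocities.
#' @param beta_windows List of `(n1, n2)` window pairs for the
#'   direction-alignment features `beta_n1_n2`.
#' @param d_windows List of `(n1, n2)` window pairs for the effective
#'   distance moved `d_n1_n2`.
#' @param smooth_windows Gaussian windows used by [derive_feature_channels()].
#' @param minmax_window Window (frames) for running min/max/cumulative.
#' @param disp_threshold Displacement status threshold, body lengths per
#'   second on the 5-frame derivative-of-Gaussian center speed.
#' @param strict_va If `TRUE`, use the literal printed agitation velocity
#'   (`v_c^2 + 2 v_nu^2`); default treats the duplicated neck-up term as a
#'   typo and uses `v_c^2 + v_nu^2 + v_nd^2`.
#' @param log_eps Floor inside log-derivative channels.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(alpha_v = 10, fourier_order = 7, deriv_window = 5,
                           beta_windows = list(c(5, 5), c(10, 10), c(15, 5), c(25, 10)),
                           d_windows = list(c(5, 5)),
                           smooth_windows = c(5, 15), minmax_window = 10,
                           disp_threshold = 0.1, strict_va = FALSE,
                           log_eps = 1e-9) {
  stopifnot(alpha_v > 0, fourier_order >= 1, deriv_window >= 2)
  structure(list(alpha_v = alpha_v, fourier_order = fourier_order,
                 deriv_window = deriv_window, beta_windows = beta_windows,
                 d_windows = d_windows, smooth_windows = smooth_windows,
                 minmax_window = minmax_window, disp_threshold = disp_threshold,
                 strict_va = strict_va, log_eps = log_eps),
            class = "feature_config")
}

#' Shape order parameter from per-segment direction cosines
#'
#' `S = (3 <cos^2 theta>_s - 1) / 2`, where theta is the angle of each
#' spine segment to the body direction. S is 1 for a perfectly straight
#' spine and -0.5 when every segment is perpendicular to the body axis.
#'
#' @param cos_theta Vector of direction cosines (one per spine segment).
#' @return The scalar order parameter in `[-0.5, 1]`.
#' @export
shape_order_parameter <- function(cos_theta) {
  (3 * mean(cos_theta^2) - 1) / 2
}

#' Contour eigen-shape factor
#'
#' `lambda = (lambda1 - lambda2) / (lambda1 + lambda2)` from the 2x2
#' coordinate covariance matrix of the contour points: 0 for a circle,
#' 1 for collinear points.
#'
#' @param points Two-column matrix of contour coordinates.
#' @return Scalar in `[0, 1]`.
#' @export
eigen_shape_factor <- function(points) {
  x <- points[, 1L] - mean(points[, 1L])
  y <- points[, 2L] - mean(points[, 2L])
  cxx <- mean(x^2); cyy <- mean(y^2); cxy <- mean(x * y)
  tr <- cxx + cyy
  if (tr <= 0) return(NA_real_)
  sqrt((cxx - cyy)^2 + 4 * cxy^2) / tr
}

angle_between <- function(ax, ay, bx, by) {
  # atan2 form: numerically stable near collinearity, unlike acos
  atan2(abs(ax * by - ay * bx), ax * bx + ay * by)
}

polygon_area <- function(x, y) {
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

contour_matrices <- function(track) {
  nc <- vapply(track$contours, nrow, integer(1))
  if (length(unique(nc)) != 1L) return(NULL)
  list(X = t(vapply(track$contours, function(m) m[, 1L], numeric(nc[1L]))),
       Y = t(vapply(track$contours, function(m) m[, 2L], numeric(nc[1L]))))
}

# ---- Fourier contour smoothing -------------------------------------------

#' Fourier smoothing of a closed contour and endpoint curvature
#'
#' Projects `x(s), y(s)` (as `z = x + iy` on the uniform contour parameter)
#' onto a truncated Fourier basis, recomposes the smooth closed curve, and
#' evaluates its signed curvature. The endpoint-curvature contrast used by
#' the head-tail model is `delta_kappa = tanh(kappa(tip1) - kappa(tip2))`
#' with the tips taken as the contour points nearest the two spine
#' endpoints.
#'
#' @param contour Two-column matrix (closed polygon, first point not
#'   repeated), at least `2 * order + 1` points.
#' @param order Truncation order (default 7).
#' @param tips Optional integer pair of contour indices at which to report
#'   curvature and their `delta_kappa`.
#' @return List with `contour` (smoothed n x 2 matrix), `kappa` (curvature
#'   at every recomposed point), and if `tips` given, `kappa_tips` and
#'   `delta_kappa`.
#' @export
smooth_contour_fourier <- function(contour, order = 7, tips = NULL) {
  n <- nrow(contour)
  if (n < 2 * order + 1) stop("contour too short for Fourier order ", order)
  z <- complex(real = contour[, 1L], imaginary = contour[, 2L])
  co <- stats::fft(z) / n
  k <- c(0L:(n - 1L))
  k <- ifelse(k > n / 2, k - n, k)
  keep <- abs(k) <= order
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  E <- exp(1i * outer(theta, k[keep]))
  ck <- co[keep]
  zs <- E %*% ck
  zp <- E %*% (1i * k[keep] * ck)
  zpp <- E %*% (-(k[keep]^2) * ck)
  kap <- Im(Conj(zp) * zpp) / (Mod(zp)^3)
  out <- list(contour = cbind(Re(zs), Im(zs)), kappa = as.numeric(kap))
  if (!is.null(tips)) {
    kt <- out$kappa[tips]
    out$kappa_tips <- kt
    out$delta_kappa <- tanh(kt[1L] - kt[2L])
  }
  out
}

# batch endpoint curvature for a track with constant contour size; the
# curvature sign is normalized by the traversal winding (counterclockwise
# positive) so that the head-tail contrast does not depend on the
# tracker's polygon orientation
fourier_tip_kappa <- function(CX, CY, tip1, tip2, order = 7) {
  n <- ncol(CX); Tn <- nrow(CX)
  nxt <- c(2:n, 1L)
  winding <- sign(rowSums(CX * CY[, nxt, drop = FALSE] -
                          CX[, nxt, drop = FALSE] * CY))
  Z <- t(CX + 1i * CY) # n x T
  C <- stats::mvfft(Z) / n
  k <- 0L:(n - 1L)
  k <- ifelse(k > n / 2, k - n, k)
  keep <- which(abs(k) <= order)
  kap_at <- function(tip_idx) {
    theta <- 2 * pi * (tip_idx - 1L) / n # length T
    zp <- zpp <- complex(length.out = Tn)
    for (j in keep) {
      kk <- k[j]
      e <- exp(1i * kk * theta) * C[j, ]
      zp <- zp + 1i * kk * e
      zpp <- zpp - kk^2 * e
    }
    winding * Im(Conj(zp) * zpp) / (Mod(zp)^3)
  }
  k1 <- kap_at(tip1); k2 <- kap_at(tip2)
  list(kappa_first = k1, kappa_last = k2, delta_kappa = tanh(k1 - k2))
}

nearest_contour_index <- function(CX, CY, px, py) {
  # per-frame index of the contour point nearest (px, py)
  d2 <- (CX - px)^2 + (CY - py)^2
  max.col(-d2, ties.method = "first")
}

# ---- geometry -------------------------------------------------------------

#' Per-frame geometric features
#'
#' Computes, for every frame: the true and modified length `l`, `l_M`; the
#' shape order parameter `S`; the contour eigen-shape factor `lambda`; the
#' four inter-segment angles `theta1..theta4`; the contour centroid,
#' surface and convex-hull surface; head-tail/head-neck/neck-tail
#' distances; and the Fourier endpoint-curvature contrast `delta_kappa`.
#' All quantities except the sign of `delta_kappa` are independent of the
#' stored endpoint order.
#'
#' @param track A `larva_track`.
#' @param cfg A [feature_config()].
#' @return Data frame with one row per frame.
#' @export
compute_geometry <- function(track, cfg = feature_config()) {
  SX <- track$spine_x; SY <- track$spine_y
  Tn <- nrow(SX)
  dx <- SX[, -1L, drop = FALSE] - SX[, -11L, drop = FALSE]
  dy <- SY[, -1L, drop = FALSE] - SY[, -11L, drop = FALSE]
  seg2 <- dx^2 + dy^2
  segn <- sqrt(seg2)
  l <- rowSums(segn)
  lM <- rowSums(seg2)
  # necks
  ndx <- (SX[, 3L] + SX[, 4L]) / 2; ndy <- (SY[, 3L] + SY[, 4L]) / 2
  nux <- (SX[, 8L] + SX[, 9L]) / 2; nuy <- (SY[, 8L] + SY[, 9L]) / 2
  midx <- SX[, 6L]; midy <- SY[, 6L]
  # body direction: lower neck -> spine midpoint
  bx <- midx - ndx; by <- midy - ndy
  bn <- sqrt(bx^2 + by^2)
  ct <- (dx * bx + dy * by) / (segn * bn)
  S <- (3 * rowMeans(ct^2) - 1) / 2
  S[bn < 1e-12 | rowSums(segn < 1e-12) > 0] <- NA_real_
  # contour-derived quantities
  lambda <- area <- hull_area <- rep(NA_real_, Tn)
  rc_x <- rowMeans(SX); rc_y <- rowMeans(SY)
  dkap <- kap1 <- kap2 <- rep(NA_real_, Tn)
  if (!is.null(track$contours)) {
    cm <- contour_matrices(track)
    if (!is.null(cm)) {
      CX <- cm$X; CY <- cm$Y
      rc_x <- rowMeans(CX); rc_y <- rowMeans(CY)
      xc <- CX - rc_x; yc <- CY - rc_y
      cxx <- rowMeans(xc^2); cyy <- rowMeans(yc^2); cxy <- rowMeans(xc * yc)
      lambda <- sqrt((cxx - cyy)^2 + 4 * cxy^2) / (cxx + cyy)
      nC <- ncol(CX)
      nxt <- c(2:nC, 1L)
      area <- abs(rowSums(CX * CY[, nxt, drop = FALSE] -
                          CX[, nxt, drop = FALSE] * CY)) / 2
      for (i in seq_len(Tn)) {
        h <- grDevices::chull(CX[i, ], CY[i, ])
        hull_area[i] <- polygon_area(CX[i, h], CY[i, h])
      }
      if (nC >= 2 * cfg$fourier_order + 1) {
        t1 <- nearest_contour_index(CX, CY, SX[, 1L], SY[, 1L])
        t2 <- nearest_contour_index(CX, CY, SX[, 11L], SY[, 11L])
        fk <- fourier_tip_kappa(CX, CY, t1, t2, cfg$fourier_order)
        kap1 <- fk$kappa_first; kap2 <- fk$kappa_last; dkap <- fk$delta_kappa
      }
    } else {
      for (i in seq_len(Tn)) {
        cc <- track$contours[[i]]
        rc_x[i] <- mean(cc[, 1L]); rc_y[i] <- mean(cc[, 2L])
        lambda[i] <- eigen_shape_factor(cc)
        area[i] <- polygon_area(cc[, 1L], cc[, 2L])
        h <- grDevices::chull(cc)
        hull_area[i] <- polygon_area(cc[h, 1L], cc[h, 2L])
        if (nrow(cc) >= 2 * cfg$fourier_order + 1) {
          t1 <- which.min((cc[, 1L] - SX[i, 1L])^2 + (cc[, 2L] - SY[i, 1L])^2)
          t2 <- which.min((cc[, 1L] - SX[i, 11L])^2 + (cc[, 2L] - SY[i, 11L])^2)
          sf <- smooth_contour_fourier(cc, cfg$fourier_order, tips = c(t1, t2))
          wind <- sign(sum(cc[, 1L] * c(cc[-1L, 2L], cc[1L, 2L]) -
                           c(cc[-1L, 1L], cc[1L, 1L]) * cc[, 2L]))
          kap1[i] <- wind * sf$kappa_tips[1L]; kap2[i] <- wind * sf$kappa_tips[2L]
          dkap[i] <- tanh(kap1[i] - kap2[i])
        }
      }
    }
  }
  # the four segments: Se1 head->neck-up, Se2 center->neck-up,
  # Se3 neck-down->center, Se4 tail->neck-down
  e1x <- nux - SX[, 11L]; e1y <- nuy - SY[, 11L]
  e2x <- nux - rc_x; e2y <- nuy - rc_y
  e3x <- rc_x - ndx; e3y <- rc_y - ndy
  e4x <- ndx - SX[, 1L]; e4y <- ndy - SY[, 1L]
  data.frame(
    l = l, l_M = lM, S = S, lambda = lambda,
    theta1 = angle_between(e1x, e1y, e3x, e3y),
    theta2 = angle_between(e4x, e4y, e2x, e2y),
    theta3 = angle_between(e1x, e1y, e2x, e2y),
    theta4 = angle_between(e3x, e3y, e4x, e4y),
    rc_x = rc_x, rc_y = rc_y, area = area, hull_area = hull_area,
    dist_head_tail = sqrt((SX[, 11L] - SX[, 1L])^2 + (SY[, 11L] - SY[, 1L])^2),
    dist_head_neck = sqrt((SX[, 11L] - SX[, 6L])^2 + (SY[, 11L] - SY[, 6L])^2),
    dist_neck_tail = sqrt((SX[, 6L] - SX[, 1L])^2 + (SY[, 6L] - SY[, 1L])^2),
    kappa_first = kap1, kappa_last = kap2, delta_kappa = dkap)
}

# ---- kinematics -----------------------------------------------------------

unit_rows <- function(vx, vy, eps = 1e-12) {
  nn <- sqrt(vx^2 + vy^2)
  ok <- nn > eps
  cbind(ifelse(ok, vx / nn, 0), ifelse(ok, vy / nn, 0))
}

#' Per-frame kinematic features
#'
#' Computes velocity, agitation, direction-alignment, effective-distance,
#' rotation-energy and auxiliary-direction channels on a uniformly sampled
#' track (see [validate_timebase()]). Windows are in frames; speeds are
#' mm/s.
#'
#' @param track A uniformly sampled `larva_track`.
#' @param cfg A [feature_config()].
#' @param geom Optional precomputed [compute_geometry()] result.
#' @return Data frame with one row per frame.
#' @export
compute_kinematics <- function(track, cfg = feature_config(), geom = NULL) {
  if (is.null(geom)) geom <- compute_geometry(track, cfg)
  dt <- stats::median(diff(track$times))
  nw <- cfg$deriv_window
  SX <- track$spine_x; SY <- track$spine_y
  vel <- function(x, y, n = nw) cbind(dog_deriv(x, n, dt), dog_deriv(y, n, dt))
  spd <- function(v) sqrt(v[, 1L]^2 + v[, 2L]^2)
  v_c <- vel(geom$rc_x, geom$rc_y)
  v_head <- vel(SX[, 11L], SY[, 11L])
  v_tail <- vel(SX[, 1L], SY[, 1L])
  v_nu <- vel((SX[, 8L] + SX[, 9L]) / 2, (SY[, 8L] + SY[, 9L]) / 2)
  v_nd <- vel((SX[, 3L] + SX[, 4L]) / 2, (SY[, 3L] + SY[, 4L]) / 2)
  v_mid <- vel(SX[, 6L], SY[, 6L])
  sc <- spd(v_c); sh <- spd(v_head); st <- spd(v_tail)
  snu <- spd(v_nu); snd <- spd(v_nd)
  va <- if (cfg$strict_va) (sc^2 + 2 * snu^2) / (3 * cfg$alpha_v) else
    (sc^2 + snu^2 + snd^2) / (3 * cfg$alpha_v)
  out <- data.frame(
    v_center = sc, v_head = sh, v_tail = st, v_neck_up = snu,
    v_neck_down = snd, v_mid = spd(v_mid), v_a = va,
    a_center = dog_deriv(sc, nw, dt), a_head = dog_deriv(sh, nw, dt),
    a_tail = dog_deriv(st, nw, dt))
  # direction-alignment family beta_n1_n2: <u>_n1 . <vhat>_n2 with u the
  # tail -> neck-down unit vector and vhat the center motion unit vector
  u <- unit_rows((SX[, 3L] + SX[, 4L]) / 2 - SX[, 1L],
                 (SY[, 3L] + SY[, 4L]) / 2 - SY[, 1L])
  vhat <- unit_rows(v_c[, 1L], v_c[, 2L], eps = 1e-9)
  for (wpair in cfg$beta_windows) {
    n1 <- wpair[1L]; n2 <- wpair[2L]
    b <- gauss_smooth(u[, 1L], n1) * gauss_smooth(vhat[, 1L], n2) +
         gauss_smooth(u[, 2L], n1) * gauss_smooth(vhat[, 2L], n2)
    out[[sprintf("beta_%d_%d", n1, n2)]] <- b
  }
  out$axis_direction_25_10 <- out[["beta_25_10"]] %||%
    (gauss_smooth(u[, 1L], 25) * gauss_smooth(vhat[, 1L], 10) +
     gauss_smooth(u[, 2L], 25) * gauss_smooth(vhat[, 2L], 10))
  # symmetrized direction evidence for head-tail decoding: the average of
  # the tail->neck-down alignment and the negated head->neck-up alignment
  # is exactly antisymmetric under a stored endpoint-order flip
  u2 <- unit_rows((SX[, 8L] + SX[, 9L]) / 2 - SX[, 11L],
                  (SY[, 8L] + SY[, 9L]) / 2 - SY[, 11L])
  out$beta_sym_10_10 <- 0.5 *
    ((gauss_smooth(u[, 1L], 10) - gauss_smooth(u2[, 1L], 10)) *
       gauss_smooth(vhat[, 1L], 10) +
     (gauss_smooth(u[, 2L], 10) - gauss_smooth(u2[, 2L], 10)) *
       gauss_smooth(vhat[, 2L], 10))
  # effective distance moved d_n1_n2 = <||G'_n1 * r_tail||>_n2
  for (wpair in cfg$d_windows) {
    n1 <- wpair[1L]; n2 <- wpair[2L]
    nm <- sqrt(dog_deriv(SX[, 1L], n1, dt)^2 + dog_deriv(SY[, 1L], n1, dt)^2)
    out[[sprintf("d_%d_%d", n1, n2)]] <- gauss_smooth(nm, n2)
  }
  # rotation energies
  d_up <- sqrt((SX[, 11L] - geom$rc_x)^2 + (SY[, 11L] - geom$rc_y)^2)
  d_low <- sqrt((SX[, 1L] - geom$rc_x)^2 + (SY[, 1L] - geom$rc_y)^2)
  out$omega_up <- d_up * dog_deriv(geom$theta1, nw, dt)^2
  out$omega_low <- d_low * dog_deriv(geom$theta2, nw, dt)^2
  # auxiliary direction variables gamma: center velocity against the unit
  # vectors of neck->head, neck->tail, tail->head and their +90 deg perps
  pairs <- list(
    neck_head = cbind(SX[, 11L] - SX[, 6L], SY[, 11L] - SY[, 6L]),
    neck_tail = cbind(SX[, 1L] - SX[, 6L], SY[, 1L] - SY[, 6L]),
    tail_head = cbind(SX[, 11L] - SX[, 1L], SY[, 11L] - SY[, 1L]))
  for (nm in names(pairs)) {
    uu <- unit_rows(pairs[[nm]][, 1L], pairs[[nm]][, 2L])
    out[[paste0("gamma_u_", nm)]] <- v_c[, 1L] * uu[, 1L] + v_c[, 2L] * uu[, 2L]
    out[[paste0("gamma_v_", nm)]] <- v_c[, 1L] * (-uu[, 2L]) + v_c[, 2L] * uu[, 1L]
  }
  # oriented evidence channels for head-tail decoding
  axis <- unit_rows(SX[, 11L] - SX[, 1L], SY[, 11L] - SY[, 1L])
  out$axial_v <- v_c[, 1L] * axis[, 1L] + v_c[, 2L] * axis[, 2L]
  out$endpoint_asym <- (sh - st) / (sh + st + 1e-9)
  # length dynamics and cluster-view frame channels
  dldt <- dog_deriv(geom$l, nw, dt)
  out$dldt <- dldt
  S10 <- gauss_smooth(ifelse(is.na(geom$S), 1, geom$S), 10)
  out$x1_frame <- log(pmax((1 - S10)^2, 1e-12))
  umid <- unit_rows(SX[, 6L] - SX[, 1L], SY[, 6L] - SY[, 1L])
  vmidhat <- unit_rows(v_mid[, 1L], v_mid[, 2L], eps = 1e-9)
  alpha_10_5 <- gauss_smooth(vmidhat[, 1L], 10) * gauss_smooth(umid[, 1L], 5) +
                gauss_smooth(vmidhat[, 2L], 10) * gauss_smooth(umid[, 2L], 5)
  out$alpha_10_5 <- alpha_10_5
  out$x3_frame <- gauss_smooth(out$v_mid, 10) / gauss_smooth(geom$l, 25) * alpha_10_5
  out$x4_frame <- gauss_smooth(dldt^2, 10)
  out$disp_status <- (sc / geom$l) > cfg$disp_threshold
  out
}

# ---- derived channels -----------------------------------------------------

#' Add smoothed, derived and normalized channels
#'
#' For each channel in `channels` and each scale in `cfg$smooth_windows`,
#' adds Gaussian-smoothed, derivative, log-derivative (log of absolute
#' derivative with a floor), squared-derivative, and windowed
#' min/max/cumulative channels. Also adds the dynamically normalized
#' channels: speeds divided by `v_l = l/dt`, per-body-length speeds,
#' contour surface divided by its convex hull and by the circumscribed
#' circle `pi (l/2)^2`, and end-to-end distances divided by `l`.
#'
#' @param ftab A feature table from [compute_features()].
#' @param cfg A [feature_config()].
#' @param channels Channel names to expand (default a compact dynamical set).
#' @return The extended feature table.
#' @export
derive_feature_channels <- function(ftab, cfg = feature_config(),
                                    channels = c("l", "S", "v_center", "v_a")) {
  dt <- attr(ftab, "dt") %||% stats::median(diff(attr(ftab, "times")))
  unknown <- setdiff(channels, names(ftab))
  if (length(unknown)) stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  for (ch in channels) {
    x <- ftab[[ch]]
    x0 <- ifelse(is.na(x), 0, x)
    for (n in cfg$smooth_windows) {
      ftab[[sprintf("%s_smooth%d", ch, n)]] <- gauss_smooth(x0, n)
      d <- dog_deriv(x0, n, dt)
      ftab[[sprintf("%s_deriv%d", ch, n)]] <- d
      ftab[[sprintf("%s_logderiv%d", ch, n)]] <- log(abs(d) + cfg$log_eps)
      ftab[[sprintf("%s_sqderiv%d", ch, n)]] <- d^2
    }
    w <- cfg$minmax_window
    ftab[[sprintf("%s_min%d", ch, w)]] <- running_min(x0, w)
    ftab[[sprintf("%s_max%d", ch, w)]] <- running_max(x0, w)
    ftab[[sprintf("%s_cum%d", ch, w)]] <- running_sum(x0, w)
  }
  l <- ftab$l
  v_l <- l / dt
  for (ch in intersect(c("v_center", "v_head", "v_tail"), names(ftab))) {
    ftab[[paste0(ch, "_vl")]] <- ftab[[ch]] / v_l
    ftab[[paste0(ch, "_bl")]] <- ftab[[ch]] / l
  }
  if (!is.null(ftab$area)) {
    ftab$area_by_hull <- ftab$area / ftab$hull_area
    ftab$area_by_circle <- ftab$area / (pi * (l / 2)^2)
  }
  for (ch in intersect(c("dist_head_tail", "dist_head_neck", "dist_neck_tail"),
                       names(ftab))) {
    ftab[[paste0(ch, "_norm")]] <- ftab[[ch]] / l
  }
  ftab
}

# ---- wrappers -------------------------------------------------------------

#' Compute the full per-frame feature table of a track
#'
#' Resamples the track on its median-dt uniform grid, computes geometry and
#' kinematics there, adds derived channels, and maps every channel back to
#' the original frames by nearest grid time.
#'
#' @param track A `larva_track`.
#' @param cfg A [feature_config()].
#' @param derive Whether to add the derived/normalized channel families.
#' @return A data frame (class `feature_table`) with one row per original
#'   frame and attributes `times`, `track_id`, `dt`.
#' @export
compute_features <- function(track, cfg = feature_config(), derive = TRUE) {
  vb <- validate_timebase(track)
  rt <- vb$resampled
  geom <- compute_geometry(rt, cfg)
  kin <- compute_kinematics(rt, cfg, geom)
  ftab <- cbind(geom, kin)
  attr(ftab, "times") <- rt$times
  attr(ftab, "dt") <- vb$stats[["median"]]
  if (derive) ftab <- derive_feature_channels(ftab, cfg)
  # map back to original frames by nearest grid time
  idx <- vapply(track$times, function(t) which.min(abs(rt$times - t)), integer(1))
  out <- ftab[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "times") <- track$times
  attr(out, "dt") <- vb$stats[["median"]]
  attr(out, "dt_stats") <- vb$stats
  attr(out, "track_id") <- track$track_id
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Whole-track global features
#'
#' Time averages over the cleaned track of the length, agitation velocity,
#' center speed and 5/5 effective distance moved. Only the length is left
#' unnormalized.
#'
#' @param ftab A feature table.
#' @return Named numeric vector `(mean_l, mean_v_a, mean_v, mean_d_5_5)`.
#' @export
global_track_features <- function(ftab) {
  c(mean_l = mean(ftab$l, na.rm = TRUE),
    mean_v_a = mean(ftab$v_a, na.rm = TRUE),
    mean_v = mean(ftab$v_center, na.rm = TRUE),
    mean_d_5_5 = mean(ftab[["d_5_5"]], na.rm = TRUE))
}

#' Cluster-view features per action event
#'
#' The three features whose per-event averages display the natural
#' clustering of larva actions: `x1 = log((1 - <S>_10)^2)`,
#' `x3 = <v>_10 / <l>_25 * alpha_10_5`, `x4 = <(dl/dt)^2>_10`, averaged
#' over each event.
#'
#' @param ftab A feature table.
#' @param events Event table from [segment_events()].
#' @return Data frame with one row per event: action, x1, x3, x4.
#' @export
cluster_view_features <- function(ftab, events) {
  if (nrow(events) == 0L) {
    return(data.frame(action = character(0), x1 = numeric(0),
                      x3 = numeric(0), x4 = numeric(0)))
  }
  res <- lapply(seq_len(nrow(events)), function(i) {
    idx <- (events$start[i] + 1L):events$end[i]
    c(x1 = mean(ftab$x1_frame[idx], na.rm = TRUE),
      x3 = mean(ftab$x3_frame[idx], na.rm = TRUE),
      x4 = mean(ftab$x4_frame[idx], na.rm = TRUE))
  })
  m <- do.call(rbind, res)
  data.frame(action = events$action, x1 = m[, "x1"], x3 = m[, "x3"],
             x4 = m[, "x4"], stringsAsFactors = FALSE)
}
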