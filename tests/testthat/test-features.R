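straight_spine_track <- function(seg = 0.4, n = 5, dt = 0.1) {
  larva_track("s", (0:(n - 1)) * dt,
              matrix(rep(seq(0, 10 * seg, by = seg), each = n), n),
              matrix(0, n, 11))
}

test_that("shape order parameter and eigen-shape factor hit their extremes", {
  # all segments perpendicular to the body axis
  expect_identical(shape_order_parameter(rep(0, 10)), -0.5)
  # straight spine along x: l = 4, l_M = 1.6, S = 1
  geom <- compute_geometry(straight_spine_track())
  expect_equal(geom$l, rep(4, 5), tolerance = 1e-12)
  expect_equal(geom$l_M, rep(1.6, 5), tolerance = 1e-12)
  expect_equal(geom$S, rep(1, 5), tolerance = 1e-12)
  # contour eigen-shape factor: circle -> 0, collinear -> 1
  th <- 2 * pi * (0:199) / 200
  expect_lt(eigen_shape_factor(cbind(cos(th), sin(th))), 1e-12)
  line <- cbind(seq(0, 1, length.out = 200), 2 * seq(0, 1, length.out = 200))
  expect_equal(eigen_shape_factor(line), 1, tolerance = 1e-12)
})

test_that("S, lambda and length bounds hold on fuzzed inputs", {
  set.seed(99)
  for (i in 1:10000) {
    sp <- matrix(cumsum(rnorm(22, sd = 0.5)), 11, 2)
    dx <- diff(sp[, 1]); dy <- diff(sp[, 2])
    segn <- sqrt(dx^2 + dy^2)
    l <- sum(segn); lM <- sum(segn^2)
    expect_true(lM <= l^2 + 1e-12)
    expect_true(lM >= l^2 / 10 - 1e-12)
  }
  # S and lambda ranges on random tracks (vector-checked per frame)
  for (s in 1:5) {
    cfg <- synthetic_config(duration = 10,
                            stimulus = stimulus_schedule(onset = 4, duration = 3),
                            seed = 300 + s)
    pl <- sample_action_sequence(cfg, 300 + s)
    g <- generate_track(pl, cfg, 300 + s)
    geom <- compute_geometry(g$track)
    expect_true(all(geom$S >= -0.5 - 1e-9 & geom$S <= 1 + 1e-9, na.rm = TRUE))
    expect_true(all(geom$lambda >= -1e-9 & geom$lambda <= 1 + 1e-9, na.rm = TRUE))
    expect_true(all(geom$l > 0))
  }
})

test_that("Fourier contour smoothing reproduces circles and ranks orders", {
  R <- 1.7
  th <- 2 * pi * (0:99) / 100
  circle <- cbind(R * cos(th), R * sin(th))
  sf <- smooth_contour_fourier(circle, order = 7, tips = c(1L, 51L))
  expect_lt(max(abs(sf$contour - circle)), 1e-10)
  expect_equal(abs(sf$kappa_tips), c(1 / R, 1 / R), tolerance = 1e-9)
  expect_equal(sf$delta_kappa, 0, tolerance = 1e-9)
  # 2:1 ellipse sampled uniformly by arc length (tracker-style): the
  # order-7 reconstruction beats order-3
  tf <- seq(0, 2 * pi, length.out = 20001)
  exf <- 2 * cos(tf); eyf <- sin(tf)
  s <- cumsum(c(0, sqrt(diff(exf)^2 + diff(eyf)^2)))
  pick <- findInterval(seq(0, max(s) * 0.99999, length.out = 100), s)
  ell <- cbind(exf[pick], eyf[pick])
  e7 <- smooth_contour_fourier(ell, order = 7)$contour
  e3 <- smooth_contour_fourier(ell, order = 3)$contour
  expect_lt(sqrt(mean((e7 - ell)^2)), sqrt(mean((e3 - ell)^2)))
  # mirror-imaging negates the endpoint curvature contrast
  egg <- cbind((1 + 0.3 * cos(th)) * cos(th), 0.8 * (1 + 0.3 * cos(th)) * sin(th))
  s1 <- smooth_contour_fourier(egg, tips = c(1L, 51L))
  mir <- cbind(-egg[, 1], egg[, 2])
  s2 <- smooth_contour_fourier(mir, tips = c(1L, 51L))
  expect_equal(s2$delta_kappa, -s1$delta_kappa, tolerance = 1e-9)
  expect_error(smooth_contour_fourier(circle[1:10, ], order = 7), "too short")
})

test_that("convolution features equal direct-summation oracles", {
  set.seed(5)
  x <- cumsum(rnorm(100))
  for (n in c(5, 10, 15, 25)) {
    expect_lt(max(abs(gauss_smooth(x, n) - oracle_conv(x, oracle_gauss_kernel(n)))),
              1e-10)
    expect_lt(max(abs(dog_deriv(x, n, 0.1) -
                      oracle_conv(x, oracle_dog_kernel(n)) / 0.1)), 1e-10)
  }
  # beta and d channels on a 100-frame synthetic track
  cfg <- synthetic_config(duration = 10, noise_mm = 0,
                          stimulus = stimulus_schedule(onset = 100), seed = 17)
  plan <- data.frame(action = "Crawl", duration = 10, t_start = 0)
  g <- generate_track(plan, cfg, 17)
  rt <- validate_timebase(g$track)$resampled
  geom <- compute_geometry(rt)
  kin <- compute_kinematics(rt, feature_config(), geom)
  dt <- median(diff(rt$times))
  # oracle: recompute beta_10_10 from first principles
  u_raw <- cbind((rt$spine_x[, 3] + rt$spine_x[, 4]) / 2 - rt$spine_x[, 1],
                 (rt$spine_y[, 3] + rt$spine_y[, 4]) / 2 - rt$spine_y[, 1])
  u <- u_raw / sqrt(rowSums(u_raw^2))
  vx <- oracle_conv(geom$rc_x, oracle_dog_kernel(5)) / dt
  vy <- oracle_conv(geom$rc_y, oracle_dog_kernel(5)) / dt
  sp <- sqrt(vx^2 + vy^2)
  vh <- cbind(ifelse(sp > 1e-9, vx / sp, 0), ifelse(sp > 1e-9, vy / sp, 0))
  g10 <- oracle_gauss_kernel(10)
  beta_oracle <- oracle_conv(u[, 1], g10) * oracle_conv(vh[, 1], g10) +
    oracle_conv(u[, 2], g10) * oracle_conv(vh[, 2], g10)
  expect_lt(max(abs(kin$beta_10_10 - beta_oracle)), 1e-10)
  # oracle for d_5_5
  tx <- oracle_conv(rt$spine_x[, 1], oracle_dog_kernel(5)) / dt
  ty <- oracle_conv(rt$spine_y[, 1], oracle_dog_kernel(5)) / dt
  d_oracle <- oracle_conv(sqrt(tx^2 + ty^2), oracle_gauss_kernel(5))
  expect_lt(max(abs(kin$d_5_5 - d_oracle)), 1e-10)
  # running min/max/cumulative against plain loops
  rw <- function(x, w, f) vapply(seq_along(x), function(i) {
    hi <- min(length(x), max(1, i - w %/% 2) + w - 1)
    lo <- max(1, hi - w + 1)
    f(x[lo:hi])
  }, numeric(1))
  expect_equal(running_min(x, 10), rw(x, 10, min), tolerance = 1e-12)
  expect_equal(running_max(x, 10), rw(x, 10, max), tolerance = 1e-12)
  expect_equal(running_sum(x, 10), rw(x, 10, sum), tolerance = 1e-12)
})

test_that("kinematics vanish for stationary larvae and saturate for axial motion", {
  # stationary: agitation and effective distance are zero
  tr <- straight_spine_track(n = 60)
  ft <- compute_features(tr, derive = FALSE)
  expect_true(all(abs(ft$v_a) < 1e-12))
  expect_true(all(abs(ft$d_5_5) < 1e-12))
  # straight larva translating along its tail->head axis: beta = +1
  # (asserted away from the track edges, where the reflected padding of
  # the derivative kernels makes the motion direction degenerate)
  mv <- straight_moving_track(n = 80)
  ftm <- compute_features(mv, derive = FALSE)
  core <- 14:66
  for (ch in c("beta_5_5", "beta_10_10", "beta_15_5", "beta_25_10")) {
    expect_true(all(abs(ftm[[ch]][core] - 1) < 1e-9))
  }
  # constant-speed crawl: d_5_5 equals the commanded speed
  expect_equal(ftm$d_5_5[core], rep(0.5, length(core)), tolerance = 1e-9)
})

test_that("rigid motions leave scalar features invariant", {
  cfg <- synthetic_config(duration = 12, noise_mm = 0,
                          stimulus = stimulus_schedule(onset = 5, duration = 4),
                          seed = 23)
  pl <- sample_action_sequence(cfg, 23)
  g <- generate_track(pl, cfg, 23)
  tr <- g$track
  ang <- 0.83; R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  shift <- c(5.2, -3.1)
  tr2 <- tr
  xy <- cbind(as.vector(tr$spine_x), as.vector(tr$spine_y)) %*% t(R)
  tr2$spine_x <- matrix(xy[, 1] + shift[1], nrow(tr$spine_x))
  tr2$spine_y <- matrix(xy[, 2] + shift[2], nrow(tr$spine_y))
  tr2$contours <- lapply(tr$contours, function(m)
    sweep(m %*% t(R), 2, -shift))
  f1 <- compute_features(tr, derive = FALSE)
  f2 <- compute_features(tr2, derive = FALSE)
  for (ch in c("S", "lambda", "l", "l_M", "theta1", "theta2", "theta3",
               "theta4", "v_a", "d_5_5", "omega_up", "omega_low",
               "beta_10_10", "v_center")) {
    expect_lt(max(abs(f1[[ch]] - f2[[ch]]), na.rm = TRUE), 1e-9)
  }
})

test_that("derived channels behave on degenerate and normalized cases", {
  tr <- straight_spine_track(n = 60)
  ft <- compute_features(tr, derive = TRUE)
  # constant channel: derivative identically zero, cumulative = value * window
  expect_true(all(abs(ft$l_deriv5) < 1e-9))
  expect_equal(ft$l_cum10[30], ft$l[30] * 10, tolerance = 1e-9)
  # straight larva: head-tail distance over l is 1
  expect_equal(ft$dist_head_tail_norm, rep(1, 60), tolerance = 1e-6)
  expect_error(derive_feature_channels(ft, channels = "nonexistent"),
               "unknown channel")
  # folded spine: ratio well below 0.2
  n <- 30
  fold_x <- c(seq(0, 2, length.out = 6), seq(1.68, 0.4, length.out = 5))
  folded <- larva_track("f", (0:(n - 1)) * 0.1,
                        matrix(rep(fold_x, each = n), n),
                        matrix(rep(c(rep(0, 6), rep(0.08, 5)), each = n), n))
  ftf <- compute_features(folded, derive = TRUE)
  expect_lt(ftf$dist_head_tail_norm[15], 0.2)
  # circular contour: area over circumscribed circle equals 1 when the
  # spine length equals the diameter
  Rr <- 2
  th <- 2 * pi * (0:199) / 200
  circ <- lapply(1:30, function(i) cbind(Rr * cos(th), Rr * sin(th)))
  trc <- larva_track("c", (0:29) * 0.1,
                     matrix(rep(seq(-Rr, Rr, length.out = 11), each = 30), 30),
                     matrix(0, 30, 11), contours = circ)
  ftc <- compute_features(trc, derive = TRUE)
  expect_equal(ftc$area_by_circle, rep(1, 30), tolerance = 1e-3)
  expect_equal(ftc$area_by_hull, rep(1, 30), tolerance = 1e-6)
})

test_that("global track features average the frame channels", {
  tr <- straight_spine_track(n = 60)
  ft <- compute_features(tr)
  gf <- global_track_features(ft)
  expect_equal(unname(gf["mean_l"]), 4, tolerance = 1e-9)
  expect_equal(unname(gf["mean_v_a"]), 0, tolerance = 1e-12)
  expect_equal(unname(gf["mean_v"]), 0, tolerance = 1e-12)
  expect_equal(unname(gf["mean_d_5_5"]), 0, tolerance = 1e-12)
  # equals an independent frame-wise summation oracle
  cfg <- synthetic_config(duration = 10, stimulus = stimulus_schedule(onset = 100),
                          seed = 71)
  plan <- data.frame(action = "Crawl", duration = 10, t_start = 0)
  g <- generate_track(plan, cfg, 71)
  ftc <- compute_features(g$track)
  gfc <- global_track_features(ftc)
  expect_equal(unname(gfc["mean_l"]), sum(ftc$l) / length(ftc$l), tolerance = 1e-12)
  expect_equal(unname(gfc["mean_d_5_5"]), sum(ftc$d_5_5) / nrow(ftc), tolerance = 1e-12)
  # linearity: mean of a concatenation of two equal-length halves
  h <- nrow(ftc) %/% 2
  expect_equal(unname(gfc["mean_v"]),
               (mean(ftc$v_center[1:h]) + mean(ftc$v_center[(h + 1):(2 * h)])) / 2,
               tolerance = 1e-9)
})

test_that("cluster-view features separate the kinematic classes", {
  tr <- straight_spine_track(n = 60)
  ft <- compute_features(tr)
  ev <- segment_events(rep("Stop", 60), tr$times, ft)
  cv <- cluster_view_features(ft, ev)
  expect_equal(cv$x3, 0, tolerance = 1e-9)
  expect_equal(cv$x4, 0, tolerance = 1e-12)
  expect_identical(nrow(cluster_view_features(ft, ev[0, ])), 0L)
  # hunch versus stop: x4 at least 10x larger
  cfg <- synthetic_config(noise_mm = 0, seed = 81,
                          stimulus = stimulus_schedule(onset = 100))
  plan <- data.frame(action = c("Stop", "Hunch", "Stop"),
                     duration = c(3, 1, 3), t_start = c(0, 3, 4))
  g <- generate_track(plan, cfg, 81)
  ftg <- compute_features(g$track)
  evg <- segment_events(g$truth$action, g$track$times, ftg)
  cvg <- cluster_view_features(ftg, evg)
  expect_gt(cvg$x4[cvg$action == "Hunch"],
            10 * max(cvg$x4[cvg$action == "Stop"]))
  # mixed population: positive silhouette of (x1, x3, x4) by true class
  pops <- lapply(1:6, function(s) {
    cfgs <- synthetic_config(duration = 25, seed = 400 + s,
                             stimulus = stimulus_schedule(onset = 10, duration = 8))
    pl <- sample_action_sequence(cfgs, 400 + s)
    g <- generate_track(pl, cfgs, 400 + s)
    ftx <- compute_features(g$track)
    evx <- segment_events(g$truth$action, g$track$times, ftx)
    cluster_view_features(ftx, evx)
  })
  cv_all <- do.call(rbind, pops)
  cv_all <- cv_all[cv_all$action %in% c("Crawl", "Stop", "Hunch") &
                   is.finite(cv_all$x1), ]
  X <- scale(cv_all[, c("x1", "x3", "x4")])
  lab <- cv_all$action
  # silhouette oracle (plain loops)
  D <- as.matrix(dist(X))
  sil <- vapply(seq_len(nrow(X)), function(i) {
    a <- mean(D[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(g2) mean(D[i, lab == g2]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil, na.rm = TRUE), 0)
})
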