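test_that("behavior probabilities partition the active population", {
  # 10 larvae tracked over [0, 10): 4 crawl, 6 bend throughout
  ethos <- c(lapply(1:4, function(i)
    make_simple_ethogram(paste0("c", i), rep("Crawl", 100))),
    lapply(1:6, function(i)
      make_simple_ethogram(paste0("b", i), rep("Bend", 100))))
  es <- ethogram_set("toy", ethos, stimulus_schedule(onset = 5, duration = 2))
  pts <- behavior_probability_timeseries(es, t_range = c(0, 9.8))
  expect_equal(unname(pts$P[, "Crawl"]), rep(0.4, length(pts$time)))
  expect_equal(unname(pts$P[, "Bend"]), rep(0.6, length(pts$time)))
  expect_true(all(abs(rowSums(pts$P) - 1) < 1e-12))
  expect_true(all(pts$n_active == 10))
  # a single larva yields an indicator trace
  one <- ethogram_set("one", list(make_simple_ethogram("x",
    c(rep("Crawl", 50), rep("Hunch", 50)))), stimulus_schedule(onset = 5))
  p1 <- behavior_probability_timeseries(one, t_range = c(0, 9.8))
  expect_true(all(p1$P[!is.na(p1$P[, 1]), ] %in% c(0, 1)))
  # windows with no active larva are NA, not zero
  p2 <- behavior_probability_timeseries(one, t_range = c(0, 20))
  expect_true(anyNA(p2$P[, "Crawl"]))
})

test_that("dominant behaviors use the fixed tie-break order", {
  pts <- list(time = c(1, 2),
              P = rbind(c(0.5, 0.3, 0.2, 0, 0, 0, 0),
                        c(0.4, 0.4, 0.2, 0, 0, 0, 0)),
              n_active = c(10, 10))
  colnames(pts$P) <- action_states()
  class(pts) <- "probability_timeseries"
  dom <- dominant_behaviors(pts)
  expect_identical(dom$dominant, c("Crawl", "Crawl"))
  expect_identical(dom$second, c("Bend", "Bend"))
})

test_that("window probabilities equal a brute-force per-frame tally", {
  # analytic cases
  st <- stimulus_schedule(onset = 2, duration = 1)
  full_bend <- make_simple_ethogram("fb", rep("Bend", 100))
  es1 <- ethogram_set("l", list(full_bend), st)
  wp <- window_probabilities(es1, st, windows = 1)
  expect_equal(wp$value[wp$reference == "onset" & wp$action == "Bend"], 1)
  half <- make_simple_ethogram("h", c(rep("Crawl", 20),
                                      rep("Hunch", 5), rep("Bend", 75)))
  es2 <- ethogram_set("l", list(half), st)
  wp2 <- window_probabilities(es2, st, windows = 1)
  expect_equal(wp2$value[wp2$reference == "onset" & wp2$action == "Hunch"],
               0.5, tolerance = 1e-12)
  expect_equal(wp2$value[wp2$reference == "onset" & wp2$action == "Bend"],
               0.5, tolerance = 1e-12)
  # oracle comparison on 50 synthetic larvae
  cfg <- synthetic_config(n_larvae = 50, duration = 50, seed = 88)
  es <- simulate_ethograms(cfg, 88)
  wp3 <- window_probabilities(es, windows = c(1, 5))
  for (w in c(1, 5)) for (ref in c("onset", "offset")) {
    t0 <- if (ref == "onset") 45 else 83
    t1 <- t0 + w
    fracs <- matrix(0, 0, 7)
    for (e in es$ethograms) {
      if (e$times[1] > t0 || e$times[length(e$times)] < t1) next
      i <- which(e$times >= t0 & e$times < t1)
      if (!length(i)) next
      nxt <- c(e$times[-1], e$times[length(e$times)] + 0.082)
      dtf <- pmin(nxt[i], t1) - e$times[i]
      tf <- vapply(action_states(), function(a) sum(dtf[e$actions[i] == a]),
                   numeric(1))
      fracs <- rbind(fracs, tf / sum(tf))
    }
    if (!nrow(fracs)) next
    for (k in 1:7) {
      got <- wp3$value[wp3$reference == ref & wp3$window == w &
                       wp3$action == action_states()[k]]
      expect_equal(got, mean(fracs[, k]), tolerance = 1e-12)
    }
  }
})

test_that("cumulative counts use at-least-once semantics", {
  st <- stimulus_schedule(onset = 1, duration = 1)
  a1 <- c(rep("Crawl", 15), "Hunch", rep("Crawl", 84)) # one 1-frame hunch
  a2 <- c(rep("Crawl", 12), "Hunch", "Crawl", "Hunch", "Crawl", "Hunch",
          rep("Crawl", 83)) # three hunches
  es <- ethogram_set("l", list(make_simple_ethogram("a", a1),
                               make_simple_ethogram("b", a2)), st)
  cc <- cumulative_counts(es, st, windows = 1)
  hu <- cc[cc$reference == "onset" & cc$action == "Hunch", ]
  expect_equal(hu$count, 2)
  expect_equal(hu$n_larvae, 2)
  expect_equal(hu$fraction, 1)
  cr <- cc[cc$reference == "onset" & cc$action == "Crawl", ]
  expect_equal(cr$count, 2)
  # the "ever" mode of window_probabilities delegates here
  wv <- window_probabilities(es, st, windows = 1, mode = "ever")
  expect_equal(wv$value[wv$reference == "onset" & wv$action == "Hunch"], 1)
})

test_that("transition matrices count event adjacencies with zero diagonal", {
  st <- stimulus_schedule(onset = 0, duration = 3)
  seq1 <- c(rep("Crawl", 10), rep("Bend", 10), rep("Hunch", 10),
            rep("Bend", 10), rep("Crawl", 10))
  es <- ethogram_set("l", list(make_simple_ethogram("a", seq1)), st)
  tm <- transition_matrix(es, window = c(0, 10))
  expect_equal(unname(tm$probabilities["Bend", "Hunch"]), 0.5)
  expect_equal(unname(tm$probabilities["Bend", "Crawl"]), 0.5)
  expect_equal(sum(tm$counts), 4)
  expect_true(all(diag(tm$counts) == 0))
  rs <- rowSums(tm$probabilities, na.rm = TRUE)
  expect_true(all(rs[rowSums(tm$counts) > 0] - 1 < 1e-12))
  # brute-force adjacency scan on 100 random ethograms
  set.seed(14)
  ethos <- lapply(1:100, function(i) {
    runs <- sample(2:8, 1)
    acts <- character(0)
    prev <- ""
    for (r in seq_len(runs)) {
      a <- sample(setdiff(action_states()[1:5], prev), 1)
      acts <- c(acts, rep(a, sample(2:10, 1)))
      prev <- a
    }
    make_simple_ethogram(paste0("r", i), acts)
  })
  esr <- ethogram_set("r", ethos, st)
  win <- c(0, 4)
  tmr <- transition_matrix(esr, window = win)
  oracle <- matrix(0L, 7, 7, dimnames = list(action_states(), action_states()))
  for (e in ethos) {
    a <- e$actions
    for (i in seq_len(length(a) - 1)) {
      if (a[i] != a[i + 1]) {
        tsw <- e$times[i + 1]
        if (tsw >= win[1] && tsw < win[2]) {
          oracle[a[i], a[i + 1]] <- oracle[a[i], a[i + 1]] + 1L
        }
      }
    }
  }
  expect_identical(unname(tmr$counts), unname(oracle))
})

test_that("estimated transition probabilities match the generating matrix", {
  cfg <- synthetic_config(n_larvae = 1500, duration = 44, seed = 15)
  es <- simulate_ethograms(cfg, 15)
  tm <- transition_matrix(es, window = c(0, 44))
  expect_gte(sum(tm$counts), 10000)
  P <- cfg$transition_pre
  # pooled goodness of fit over all rows (one matrix-level test)
  chi <- 0; df <- 0
  for (a in action_states()) {
    row <- tm$counts[a, ]
    if (sum(row) < 100) next
    keep <- P[a, ] > 0
    expect_true(all(row[!keep] == 0)) # unsupported transitions never occur
    e <- sum(row) * P[a, keep]
    chi <- chi + sum((row[keep] - e)^2 / e)
    df <- df + sum(keep) - 1
  }
  expect_gt(pchisq(chi, df, lower.tail = FALSE), 0.01)
})

test_that("post-onset sequences follow the perception-uncertainty rule", {
  st <- stimulus_schedule(onset = 2, duration = 1)
  # crawling at onset, switches to Hunch 0.2 s later: sequence starts Hunch
  a1 <- c(rep("Crawl", 22), rep("Hunch", 10), rep("Bend", 68))
  es1 <- ethogram_set("l", list(make_simple_ethogram("a", a1)), st)
  s1 <- extract_sequences(es1, st)
  expect_identical(s1$action[s1$position == 1], "Hunch")
  expect_true(s1$ambiguous[1])
  # bending from before onset through onset + 0.8 s: starts Bend
  a2 <- c(rep("Crawl", 10), rep("Bend", 18), rep("Crawl", 72))
  es2 <- ethogram_set("l", list(make_simple_ethogram("b", a2)), st)
  s2 <- extract_sequences(es2, st)
  expect_identical(s2$action[s2$position == 1], "Bend")
  expect_false(s2$ambiguous[1])
  # only two post-onset events: sequence of length 2
  a3 <- c(rep("Crawl", 21), rep("Hunch", 40), rep("Stop", 39))
  es3 <- ethogram_set("l", list(make_simple_ethogram("c", a3)), st)
  s3 <- extract_sequences(es3, st)
  expect_identical(nrow(s3), 2L)
  expect_identical(s3$action, c("Hunch", "Stop"))
  # at most four actions are kept
  a4 <- c(rep("Crawl", 21), rep(c("Hunch", "Bend"), each = 5, times = 6))
  es4 <- ethogram_set("l", list(make_simple_ethogram("d", a4)), st)
  expect_identical(nrow(extract_sequences(es4, st)), 4L)
})

test_that("amplitude statistics satisfy their identities", {
  ev <- data.frame(action = c("Hunch", "Hunch", "Bend"),
                   l_min = c(8, 3.2, 3), l_max = c(10, 4, 4),
                   lM_min = c(6, 1, 1), lM_max = c(10, 1.6, 1.6),
                   S_min = c(0.2, 0.5, 0.65))
  as_ <- amplitude_stats(ev)
  expect_equal(as_$hunch$delta_l[1], 0.2, tolerance = 1e-12)
  expect_equal(as_$hunch$r_l[1], 0.8, tolerance = 1e-12)
  expect_true(all(abs(as_$hunch$delta_l + as_$hunch$r_l - 1) < 1e-12))
  expect_true(all(abs(as_$hunch$delta_lM + as_$hunch$r_lM - 1) < 1e-12))
  expect_equal(as_$bend_mean_min_S, 0.65, tolerance = 1e-12)
  expect_equal(as_$hunch$delta_l, (ev$l_max[1:2] - ev$l_min[1:2]) / ev$l_max[1:2],
               tolerance = 1e-12)
})

test_that("orientation analysis wraps angles and runs pairwise KS tests", {
  expect_equal(wrap_angle(3 * pi / 2), -pi / 2, tolerance = 1e-12)
  expect_equal(wrap_angle(-pi), pi, tolerance = 1e-12)
  # uniform angles stay inside the 95% KS band around the uniform CDF
  set.seed(21)
  th <- runif(500, -pi, pi)
  d <- max(abs(ecdf(th)(sort(th)) - (sort(th) + pi) / (2 * pi)))
  expect_lt(d, 1.358 / sqrt(500))
  # end-to-end on oriented synthetic tracks
  cfg <- synthetic_config(n_larvae = 8, duration = 50, flip_persistence = 1,
                          seed = 33)
  pop <- simulate_population(cfg, 33)
  es <- ethogram_set("synthetic", lapply(seq_along(pop$track_set$tracks),
    function(i) {
      tr <- pop$track_set$tracks[[i]]
      tru <- pop$truth[pop$truth$track_id == tr$track_id, ]
      ethogram(tr$track_id, tru$time, tru$action)
    }), cfg$stimulus)
  oa <- orientation_analysis(pop$track_set, es)
  expect_true(all(oa$records$theta > -pi & oa$records$theta <= pi))
  expect_true(all(oa$records$first_action %in% action_states()))
  if (!is.null(oa$ks)) {
    expect_true(all(oa$ks$D >= 0 & oa$ks$D <= 1))
    expect_true(all(oa$ks$p >= 0 & oa$ks$p <= 1))
  }
  # identical and disjoint samples at the KS extremes
  k0 <- amplitude_ks(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(k0$D, 0, tolerance = 1e-12)
  k1 <- amplitude_ks(c(1, 2, 3), c(10, 11, 12))
  expect_equal(k1$D, 1, tolerance = 1e-12)
})

test_that("ethogram rendering is lossless", {
  cfg <- synthetic_config(n_larvae = 3, duration = 20,
                          stimulus = stimulus_schedule(onset = 8, duration = 5),
                          seed = 44)
  es <- simulate_ethograms(cfg, 44)
  tab <- ethogram_table(es)
  for (e in es$ethograms) {
    sub <- tab[tab$track_id == e$track_id, ]
    expect_identical(sub$action, e$actions)
    expect_equal(sub$time, e$times, tolerance = 1e-12)
  }
  # splitting an event into contiguous sub-events leaves fraction-of-time
  # statistics unchanged (they are computed from frames, not events)
  st <- es$stimulus
  wp <- window_probabilities(es, st, windows = 1)
  es2 <- es
  es2$ethograms <- lapply(es$ethograms, function(e)
    ethogram(e$track_id, e$times, e$actions,
             events = segment_events(e$actions, e$times)))
  wp2 <- window_probabilities(es2, st, windows = 1)
  expect_equal(wp$value, wp2$value, tolerance = 1e-12)
})
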