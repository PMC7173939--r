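#' Screen configuration
#'
#' @param alpha Significance level for single tests.
#' @param p_tresh Primary competitive-rule threshold (the secondary
#'   threshold is `10 * p_tresh`).
#' @param P_tresh Locomotor-anomaly dominance threshold.
#' @param anomaly_T Pre-stimulus window length for the anomaly filter (s);
#'   44.75 s leaves a 250 ms guard before the 45 s onset.
#' @param response_window Post-onset window (s) for the behavior counts.
#' @param transition_window Post-onset window (s) for transition tests.
#' @param called_behaviors Behaviors used for hit calls.
#' @param count_mode `"first-response"` (a larva counts in the behavior of
#'   its first response within the window) or `"ever"` (any occurrence).
#' @param bonferroni_m Number of tested lines for the optional Bonferroni
#'   decisions (`NULL`: set from the screen).
#' @return List of class `screen_config`.
#' @export
screen_config <- function(alpha = 0.05, p_tresh = 0.01, P_tresh = 0.97,
                          anomaly_T = 44.75, response_window = 1,
                          transition_window = 3,
                          called_behaviors = c("Hunch", "Bend", "Backup"),
                          count_mode = c("first-response", "ever"),
                          bonferroni_m = NULL) {
  count_mode <- match.arg(count_mode)
  stopifnot(alpha > 0, alpha < 1, p_tresh > 0, p_tresh < 1,
            P_tresh > 0, P_tresh < 1)
  structure(list(alpha = alpha, p_tresh = p_tresh, P_tresh = P_tresh,
                 anomaly_T = anomaly_T, response_window = response_window,
                 transition_window = transition_window,
                 called_behaviors = called_behaviors,
                 count_mode = count_mode, bonferroni_m = bonferroni_m),
            class = "screen_config")
}

#' Locomotor-anomaly exclusion filter
#'
#' Over the pre-stimulus window `[0, T)`, `P1` is the fraction of 2-dt
#' windows in which Crawl is the dominant population behavior and `P2`
#' the fraction in which Bend is the second dominant. The line is kept
#' under the normal-locomotion hypothesis only if both exceed `P_tresh`
#' strictly; otherwise it is excluded as a likely locomotor defect.
#'
#' @param es An `ethogram_set`.
#' @param cfg A [screen_config()].
#' @param dt Half-window of the dominance time series (s).
#' @return List: `excluded`, `P1`, `P2`.
#' @export
locomotor_anomaly_filter <- function(es, cfg = screen_config(), dt = 0.1) {
  max_t <- max(unlist(lapply(es$ethograms, function(e) max(e$times))))
  if (max_t < cfg$anomaly_T) stop("tracks shorter than the anomaly window")
  pts <- behavior_probability_timeseries(es, dt = dt,
                                         t_range = c(0, cfg$anomaly_T - 1e-9))
  keep <- pts$time < cfg$anomaly_T
  dom <- dominant_behaviors(pts)[keep, ]
  dom <- dom[!is.na(dom$dominant), ]
  P1 <- mean(dom$dominant == "Crawl")
  P2 <- mean(dom$second == "Bend")
  list(excluded = !(P1 > cfg$P_tresh && P2 > cfg$P_tresh), P1 = P1, P2 = P2)
}

#' Binomial generalized likelihood-ratio test
#'
#' `z = -2 log [ B(pooled; n_m, N_m) B(pooled; n_0, N_0) /
#' (B(p_m; n_m, N_m) B(p_0; n_0, N_0)) ]` with the pooled proportion
#' `(n_m + n_0) / (N_m + N_0)`; `p` is the upper-tail chi-square
#' probability with one degree of freedom, and the direction is the sign
#' of `p_m - p_0`. Vectorized over its arguments; `0 log 0 = 0`.
#'
#' @param n_m,N_m Test-line count and total.
#' @param n_0,N_0 Control count and total.
#' @return Data frame: z, p, direction (+1 increase, -1 decrease, 0).
#' @export
glr_binomial <- function(n_m, N_m, n_0, N_0) {
  if (any(N_m <= 0) || any(N_0 <= 0)) stop("group totals must be positive")
  if (any(n_m < 0 | n_m > N_m | n_0 < 0 | n_0 > N_0)) stop("counts out of range")
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  ll <- function(n, N, p) xlogy(n, p) + xlogy(N - n, 1 - p)
  p_m <- n_m / N_m; p_0 <- n_0 / N_0
  p_pool <- (n_m + n_0) / (N_m + N_0)
  z <- 2 * (ll(n_m, N_m, p_m) + ll(n_0, N_0, p_0) -
            ll(n_m, N_m, p_pool) - ll(n_0, N_0, p_pool))
  z <- pmax(z, 0)
  data.frame(z = z, p = stats::pchisq(z, df = 1, lower.tail = FALSE),
             direction = sign(p_m - p_0))
}

#' Multinomial generalized likelihood-ratio test
#'
#' Two-sample G-test of the full 7-behavior distribution against the
#' control: `z = 2 sum n log(p_group / p_pooled)` over both groups and
#' all categories, `p` from chi-square with `df = 6`. Categories with
#' zero pooled count drop from the sum.
#'
#' @param counts_m,counts_0 Count vectors (7 behaviors).
#' @return List: z, p, df.
#' @export
glr_multinomial <- function(counts_m, counts_0) {
  if (sum(counts_m) <= 0 || sum(counts_0) <= 0) stop("each group needs counts")
  stopifnot(length(counts_m) == length(counts_0))
  df <- length(counts_m) - 1L
  pool <- (counts_m + counts_0) / (sum(counts_m) + sum(counts_0))
  z <- 0
  for (counts in list(counts_m, counts_0)) {
    ph <- counts / sum(counts)
    i <- counts > 0
    z <- z + 2 * sum(counts[i] * log(ph[i] / pool[i]))
  }
  list(z = max(z, 0), p = stats::pchisq(max(z, 0), df = df, lower.tail = FALSE),
       df = df)
}

#' Competitive-interaction hit rule
#'
#' Two simultaneous tests: the multinomial test must be significant at
#' `alpha`, and there must exist two called behaviors changing in
#' opposite directions with the smaller p-value below `p_tresh` and the
#' larger below `10 * p_tresh`.
#'
#' @param behavior_tests Data frame with columns behavior, p, direction
#'   (the called behaviors).
#' @param multinomial_p Multinomial GLR p-value.
#' @param cfg A [screen_config()].
#' @return Logical: competitive hit?
#' @export
competitive_hit_rule <- function(behavior_tests, multinomial_p,
                                 cfg = screen_config()) {
  if (is.na(multinomial_p) || multinomial_p >= cfg$alpha) return(FALSE)
  bt <- behavior_tests[is.finite(behavior_tests$p) & behavior_tests$direction != 0, ]
  if (nrow(bt) < 2L) return(FALSE)
  up <- bt[bt$direction > 0, ]; dn <- bt[bt$direction < 0, ]
  if (nrow(up) == 0L || nrow(dn) == 0L) return(FALSE)
  for (i in seq_len(nrow(up))) for (j in seq_len(nrow(dn))) {
    ps <- c(up$p[i], dn$p[j])
    if (min(ps) < cfg$p_tresh && max(ps) < 10 * cfg$p_tresh) return(TRUE)
  }
  FALSE
}

#' Categorize a line's phenotype
#'
#' Competitive (the rule above) takes precedence; otherwise "less" /
#' "more" when at least one called behavior is significant at `alpha`
#' with a uniform direction among the significant ones; mixed significant
#' directions that fail the competitive thresholds are reported as
#' "mixed"; otherwise "none". Excluded lines carry their exclusion.
#'
#' @param behavior_tests Data frame (behavior, p, direction).
#' @param multinomial_p Multinomial GLR p.
#' @param excluded Anomaly-filter flag.
#' @param cfg A [screen_config()].
#' @return Character category.
#' @export
classify_hits <- function(behavior_tests, multinomial_p, excluded = FALSE,
                          cfg = screen_config()) {
  if (excluded) return("excluded")
  if (competitive_hit_rule(behavior_tests, multinomial_p, cfg)) return("competitive")
  sig <- behavior_tests[is.finite(behavior_tests$p) &
                        behavior_tests$p < cfg$alpha, ]
  if (nrow(sig) == 0L) return("none")
  if (all(sig$direction > 0)) return("more")
  if (all(sig$direction < 0)) return("less")
  "mixed"
}

#' Two-sample Kolmogorov-Smirnov amplitude comparison
#'
#' @param samples_m,samples_0 Amplitude samples (at least 2 each;
#'   otherwise skipped with NA).
#' @return List: D, p (asymptotic), n_m, n_0.
#' @export
amplitude_ks <- function(samples_m, samples_0) {
  samples_m <- samples_m[is.finite(samples_m)]
  samples_0 <- samples_0[is.finite(samples_0)]
  if (length(samples_m) < 2L || length(samples_0) < 2L) {
    return(list(D = NA_real_, p = NA_real_, n_m = length(samples_m),
                n_0 = length(samples_0), note = "insufficient samples"))
  }
  kt <- suppressWarnings(stats::ks.test(samples_m, samples_0))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_m = length(samples_m), n_0 = length(samples_0), note = NA_character_)
}

#' Element-wise transition-probability tests
#'
#' For each ordered behavior pair `(k, l)`, a binomial GLR on the
#' transition count against the row total, test line versus control, plus
#' the Fisher exact test on the same 2x2 table. Pairs whose row total is
#' zero in either group are skipped.
#'
#' @param tm_m,tm_0 `transition_matrix` objects (test, control).
#' @return Data frame: from, to, T_m, T_0, z, p_glr, p_fisher.
#' @export
transition_tests <- function(tm_m, tm_0) {
  acts <- rownames(tm_m$counts)
  out <- list()
  for (k in acts) for (l in acts) {
    if (k == l) next
    Rm <- sum(tm_m$counts[k, ]); R0 <- sum(tm_0$counts[k, ])
    if (Rm == 0L || R0 == 0L) next
    nm <- tm_m$counts[k, l]; n0 <- tm_0$counts[k, l]
    g <- glr_binomial(nm, Rm, n0, R0)
    f <- stats::fisher.test(matrix(c(nm, Rm - nm, n0, R0 - n0), 2L))
    out[[length(out) + 1L]] <- data.frame(
      from = k, to = l, T_m = nm / Rm, T_0 = n0 / R0,
      z = g$z, p_glr = g$p, p_fisher = f$p.value,
      direction = g$direction, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(from = character(0), to = character(0), T_m = numeric(0),
                      T_0 = numeric(0), z = numeric(0), p_glr = numeric(0),
                      p_fisher = numeric(0), direction = numeric(0)))
  }
  do.call(rbind, out)
}

#' Bonferroni-corrected decisions
#'
#' @param p_values Numeric vector.
#' @param m Number of comparisons.
#' @param alpha Family significance level.
#' @return Data frame: p, significant (uncorrected), significant_bonf
#'   (at `alpha / m`).
#' @export
bonferroni <- function(p_values, m, alpha = 0.05) {
  stopifnot(m >= 1)
  data.frame(p = p_values, significant = p_values < alpha,
             significant_bonf = p_values < alpha / m)
}

#' First-response behavior counts of a line
#'
#' `n_m^k`: the number of larvae whose response in the post-onset window
#' is behavior k. In mode "first-response" (default) the response is the
#' larva's first action after onset (dt-blur rule of
#' [extract_sequences()]) provided it starts within the window; in mode
#' "ever" a larva counts once for every behavior it shows in the window,
#' with `N_m` the number of active larvae.
#'
#' @param es An `ethogram_set`.
#' @param cfg A [screen_config()].
#' @return List: counts (7-vector), N.
#' @export
response_counts <- function(es, cfg = screen_config()) {
  acts <- action_states()
  onset <- es$stimulus$onset
  if (cfg$count_mode == "first-response") {
    seqs <- extract_sequences(es, es$stimulus)
    first <- seqs[seqs$position == 1L, , drop = FALSE]
    counts <- tabulate(factor(first$action, levels = acts), 7L)
    N <- nrow(first)
  } else {
    counts <- stats::setNames(numeric(7L), acts)
    N <- 0L
    for (e in es$ethograms) {
      i <- window_frames(e, onset, onset + cfg$response_window)
      if (!length(i)) next
      N <- N + 1L
      seen <- unique(e$actions[i])
      counts[seen] <- counts[seen] + 1L
    }
  }
  list(counts = stats::setNames(as.numeric(counts), acts), N = N)
}

#' Run the full screen analysis
#'
#' For every test line: locomotor-anomaly filter, per-behavior binomial
#' GLR tests and the multinomial GLR against the control, the competitive
#' rule and phenotype category, and element-wise transition tests over
#' the post-onset transition window.
#'
#' @param lines Named list of `ethogram_set`s (one per line).
#' @param control_id Name of the control line in `lines`.
#' @param cfg A [screen_config()].
#' @param anomaly_filter Set `FALSE` to skip the exclusion step (e.g. for
#'   short synthetic clocks).
#' @return List of class `screen_result`: `hits` (one row per line),
#'   `behavior_tests`, `transitions`, `exclusions`.
#' @export
run_screen <- function(lines, control_id, cfg = screen_config(),
                       anomaly_filter = TRUE) {
  if (!control_id %in% names(lines)) stop("control line not found: ", control_id)
  ctrl <- lines[[control_id]]
  rc0 <- response_counts(ctrl, cfg)
  tm0 <- transition_matrix(ctrl, ctrl$stimulus$onset + c(0, cfg$transition_window))
  test_ids <- setdiff(names(lines), control_id)
  m_bonf <- cfg$bonferroni_m %||% length(test_ids)
  hits <- list(); bt_all <- list(); tr_all <- list(); excl <- list()
  for (id in test_ids) {
    es <- lines[[id]]
    ex <- list(excluded = FALSE, P1 = NA_real_, P2 = NA_real_)
    if (anomaly_filter) ex <- locomotor_anomaly_filter(es, cfg)
    excl[[id]] <- data.frame(line_id = id, excluded = ex$excluded,
                             P1 = ex$P1, P2 = ex$P2, stringsAsFactors = FALSE)
    if (ex$excluded) {
      hits[[id]] <- data.frame(line_id = id, category = "excluded",
                               multinomial_p = NA_real_, N = NA_integer_,
                               stringsAsFactors = FALSE)
      next
    }
    rc <- response_counts(es, cfg)
    if (rc$N == 0L || rc0$N == 0L) {
      hits[[id]] <- data.frame(line_id = id, category = "none",
                               multinomial_p = NA_real_, N = rc$N,
                               stringsAsFactors = FALSE)
      next
    }
    g_all <- glr_binomial(rc$counts, rc$N, rc0$counts, rc0$N)
    bt <- data.frame(line_id = id, behavior = action_states(),
                     n_m = rc$counts, N_m = rc$N, n_0 = rc0$counts,
                     N_0 = rc0$N, z = g_all$z, p = g_all$p,
                     direction = g_all$direction,
                     significant_bonf = g_all$p < cfg$alpha / m_bonf,
                     stringsAsFactors = FALSE)
    bt_all[[id]] <- bt
    mult <- glr_multinomial(rc$counts, rc0$counts)
    called <- bt[bt$behavior %in% cfg$called_behaviors, ]
    category <- classify_hits(called, mult$p, FALSE, cfg)
    tm <- transition_matrix(es, es$stimulus$onset + c(0, cfg$transition_window))
    tt <- transition_tests(tm, tm0)
    if (nrow(tt)) tr_all[[id]] <- cbind(line_id = id, tt)
    hits[[id]] <- data.frame(line_id = id, category = category,
                             multinomial_p = mult$p, N = rc$N,
                             stringsAsFactors = FALSE)
  }
  structure(list(
    hits = do.call(rbind, c(hits, list(make.row.names = FALSE))),
    behavior_tests = if (length(bt_all))
      do.call(rbind, c(bt_all, list(make.row.names = FALSE))) else NULL,
    transitions = if (length(tr_all))
      do.call(rbind, c(tr_all, list(make.row.names = FALSE))) else NULL,
    exclusions = do.call(rbind, c(excl, list(make.row.names = FALSE))),
    control_id = control_id, cfg = cfg), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result: %d lines vs control %s>\n",
              nrow(x$hits), x$control_id))
  print(table(x$hits$category))
  invisible(x)
}
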