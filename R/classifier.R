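#' Classifier configuration
#'
#' @param frame_features Per-frame channels used by the frame-level layers
#'   (those absent from a feature table are silently dropped, so contour-
#'   free tracks remain classifiable).
#' @param prob_smooth_window Gaussian window (frames) applied to layer-1
#'   probabilities before they feed layers 3/4.
#' @param backup_axis_threshold Back-up rule cutoff on
#'   `axis_direction_25_10` (the printed value is -0.8).
#' @param min_event_frames Stop/Backup events shorter than this many
#'   frames are merged into a neighbor.
#' @param legacy_dl Legacy hunch threshold on `l_min/l_max`.
#' @param legacy_S Legacy bend threshold on the minimal S.
#' @param ntree Trees per random forest.
#' @param max_train_frames Total frame budget for layer training
#'   (stratified by class, which also concentrates sampling on the
#'   stimulus-locked actions).
#' @param seed Training seed.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(
    frame_features = c("S", "lambda", "l_rel", "dldt_bl", "x1_frame",
                       "x3_frame", "x4_frame", "alpha_10_5", "v_center_bl",
                       "v_head_bl", "v_tail_bl", "v_a", "beta_5_5",
                       "beta_10_10", "beta_15_5", "axis_direction_25_10",
                       "d_5_5", "omega_up", "omega_low", "theta1", "theta2",
                       "dist_head_tail_norm", "area_by_circle"),
    prob_smooth_window = 5, backup_axis_threshold = -0.8,
    min_event_frames = 2L, legacy_dl = 0.8, legacy_S = 0.81,
    ntree = 100L, max_train_frames = 24000L, seed = 1L) {
  stopifnot(is.finite(backup_axis_threshold))
  structure(list(frame_features = frame_features,
                 prob_smooth_window = prob_smooth_window,
                 backup_axis_threshold = backup_axis_threshold,
                 min_event_frames = as.integer(min_event_frames),
                 legacy_dl = legacy_dl, legacy_S = legacy_S,
                 ntree = as.integer(ntree),
                 max_train_frames = as.integer(max_train_frames),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

prepare_frame_features <- function(ftab, cfg) {
  df <- as.data.frame(ftab)
  df$l_rel <- df$l / mean(df$l, na.rm = TRUE)
  df$dldt_bl <- df$dldt / df$l
  keep <- intersect(cfg$frame_features, names(df))
  X <- df[, keep, drop = FALSE]
  X[] <- lapply(X, function(v) { v[!is.finite(v)] <- 0; v })
  X
}

#' Rule-based postural labels from geometry
#'
#' Static shape classes used to train the posture classifier: Ball and
#' Curl from the folded head-tail distance, Bend and StraightLightBend
#' from the shape order parameter, Straight otherwise.
#'
#' @param ftab A feature table.
#' @return Factor of posture states.
#' @export
posture_from_geometry <- function(ftab) {
  ht <- ftab$dist_head_tail / ftab$l
  S <- ifelse(is.na(ftab$S), 1, ftab$S)
  p <- ifelse(ht < 0.35, "Ball",
       ifelse(ht < 0.6, "Curl",
       ifelse(S < 0.81, "Bend",
       ifelse(S < 0.95, "StraightLightBend", "Straight"))))
  factor(p, levels = posture_states())
}

rf_fit <- function(X, y, ntree, seed) {
  set.seed(seed)
  randomForest::randomForest(x = X, y = y, ntree = ntree)
}

smooth_prob_matrix <- function(P, n) {
  apply(P, 2L, gauss_smooth, n = n)
}

# ---- training -------------------------------------------------------------

#' Train the full multilayer action classifier
#'
#' Incremental supervised training on ground-truth-labeled tracks: layer-1
#' per-action binary detectors and the posture classifier; the layer-3/4
#' multiclass model on features plus the layer-1/2 states and smoothed
#' probabilities; the event-level hunch-correction classifier; and the
#' layer-5 finalizer pair (random forest + support vector machine) on
#' duration-aggregated event features. Deterministic given `seed`.
#'
#' @param corpus List of per-larva records `list(ftab, actions)` (see
#'   [labeled_corpus()]).
#' @param cfg A [classifier_config()].
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return List of class `trained_models`.
#' @export
train_pipeline <- function(corpus, cfg = classifier_config(), seed = cfg$seed) {
  acts <- action_states()
  Xs <- lapply(corpus, function(r) prepare_frame_features(r$ftab, cfg))
  ys <- lapply(corpus, function(r) action_factor(r$actions))
  X <- do.call(rbind, Xs)
  y <- unlist(lapply(ys, as.character))
  post <- unlist(lapply(corpus, function(r) as.character(posture_from_geometry(r$ftab))))
  # stratified subsample: equal per-class quota within the frame budget
  set.seed(seed)
  present <- intersect(acts, unique(y))
  quota <- ceiling(cfg$max_train_frames / length(present))
  idx <- unlist(lapply(present, function(a) {
    i <- which(y == a)
    if (length(i) > quota) sample(i, quota) else i
  }))
  idx <- sort(idx)
  Xi <- X[idx, , drop = FALSE]; yi <- y[idx]; pi_ <- post[idx]
  missing_classes <- setdiff(setdiff(acts, "Backup"), unique(y))
  if (length(missing_classes)) {
    warning("class(es) absent from training data, never predicted: ",
            paste(missing_classes, collapse = ", "))
  }
  layer1 <- stats::setNames(vector("list", 7L), acts)
  for (a in setdiff(acts, "Backup")) { # Backup is rule-defined in layer 1
    if (!a %in% yi) next
    layer1[[a]] <- rf_fit(Xi, factor(yi == a, levels = c(FALSE, TRUE)),
                          cfg$ntree, seed + match(a, acts))
  }
  posture_rf <- rf_fit(Xi, droplevels(factor(pi_, levels = posture_states())),
                       cfg$ntree, seed + 11L)
  models <- structure(list(layer1 = layer1, posture = posture_rf,
                           layer34 = NULL, hunch = NULL,
                           layer5_rf = NULL, layer5_svm = NULL,
                           feat_names = colnames(X), cfg = cfg, seed = seed,
                           classes = present),
                      class = "trained_models")
  # layer 2 states on the training corpus feed layers 3/4
  l34_X <- vector("list", length(corpus))
  for (k in seq_along(corpus)) {
    l1 <- layer1_detect(corpus[[k]]$ftab, models)
    l2 <- hierarchy_regularize(l1$booleans)
    l34_X[[k]] <- layer34_design(Xs[[k]], l2, l1$action_probs, cfg)
  }
  X34 <- do.call(rbind, l34_X)
  models$layer34 <- rf_fit(X34[idx, , drop = FALSE],
                           factor(yi, levels = present), cfg$ntree, seed + 21L)
  # event-level layers, trained on the layer-3/4 output of the corpus
  ev_feats <- list(); ev_lab <- list(); ev_truth <- list()
  for (k in seq_along(corpus)) {
    st <- layer34_classify(corpus[[k]]$ftab, NULL, NULL, models,
                           design = l34_X[[k]])
    st <- regularize_singular(st)
    evs <- segment_events(st, attr(corpus[[k]]$ftab, "times"), corpus[[k]]$ftab)
    if (nrow(evs) == 0L) next
    ef <- event_features(evs, corpus[[k]]$ftab)
    truth_ev <- vapply(seq_len(nrow(evs)), function(i) {
      fr <- (evs$start[i] + 1L):evs$end[i]
      names(which.max(table(as.character(ys[[k]])[fr])))
    }, character(1))
    ev_feats[[k]] <- ef; ev_lab[[k]] <- evs$action; ev_truth[[k]] <- truth_ev
  }
  EF <- do.call(rbind, ev_feats)
  elab <- unlist(ev_lab); etruth <- unlist(ev_truth)
  hz <- which(elab == "Hunch")
  if (length(hz) >= 10L) {
    is_true <- etruth[hz] == "Hunch"
    if (length(unique(is_true)) == 2L) {
      models$hunch <- rf_fit(EF[hz, , drop = FALSE],
                             factor(is_true, levels = c(FALSE, TRUE)),
                             cfg$ntree, seed + 31L)
    } else if (all(is_true)) {
      # every candidate was a genuine hunch: nothing to differentiate
      models$hunch <- "keep-all"
    }
  }
  keep_ev <- etruth %in% present
  ev_present <- intersect(present, unique(etruth[keep_ev]))
  keep_ev <- etruth %in% ev_present
  models$layer5_rf <- rf_fit(EF[keep_ev, , drop = FALSE],
                             factor(etruth[keep_ev], levels = ev_present),
                             cfg$ntree, seed + 41L)
  set.seed(seed + 51L)
  models$layer5_svm <- e1071::svm(x = as.matrix(EF[keep_ev, , drop = FALSE]),
                                  y = factor(etruth[keep_ev], levels = ev_present),
                                  probability = TRUE, kernel = "radial")
  models
}

#' Build a labeled feature corpus from synthetic tracks
#'
#' Orients each track with the head-tail HMM, computes its feature table,
#' and aligns the ground-truth per-frame actions.
#'
#' @param pop Result of [simulate_population()].
#' @param fcfg A [feature_config()].
#' @param orient Whether to run the orientation HMM (set `FALSE` if tracks
#'   are known oriented).
#' @return List of per-larva records `list(ftab, actions, track)`.
#' @export
labeled_corpus <- function(pop, fcfg = feature_config(), orient = TRUE) {
  lapply(seq_along(pop$track_set$tracks), function(i) {
    tr <- pop$track_set$tracks[[i]]
    if (orient) tr <- orient_track(tr, cfg = fcfg)$track
    ftab <- compute_features(tr, fcfg)
    truth <- pop$truth[pop$truth$track_id == tr$track_id, ]
    list(ftab = ftab, actions = truth$action, track = tr)
  })
}

# ---- layers ---------------------------------------------------------------

#' Layer 1: independent per-action detection and postural state
#'
#' Each action detector outputs a Boolean per frame; Backup is forced by
#' the printed rule: posture in (Straight, StraightLightBend) AND
#' displacement status AND `axis_direction_25_10 < -0.8`. Detectors for
#' classes absent at training never fire.
#'
#' @param ftab Feature table.
#' @param models A `trained_models`.
#' @return List with `booleans` (T x 7 logical), `action_probs` (T x 7),
#'   `posture_probs` (T x 5), `posture` (factor), `disp_status`.
#' @export
layer1_detect <- function(ftab, models) {
  cfg <- models$cfg
  X <- prepare_frame_features(ftab, cfg)
  if (!identical(colnames(X), models$feat_names)) {
    miss <- setdiff(models$feat_names, colnames(X))
    if (length(miss)) stop("missing feature channels: ", paste(miss, collapse = ", "))
    X <- X[, models$feat_names, drop = FALSE]
  }
  acts <- action_states()
  Tn <- nrow(X)
  probs <- matrix(0, Tn, 7L, dimnames = list(NULL, acts))
  for (a in acts) {
    if (!is.null(models$layer1[[a]])) {
      probs[, a] <- stats::predict(models$layer1[[a]], X, type = "prob")[, "TRUE"]
    }
  }
  pp0 <- stats::predict(models$posture, X, type = "prob")
  pp <- matrix(0, Tn, 5L, dimnames = list(NULL, posture_states()))
  pp[, colnames(pp0)] <- pp0
  posture <- posture_regularize(pp)
  disp <- as.logical(ftab$disp_status)
  disp[is.na(disp)] <- FALSE
  bools <- probs >= 0.5
  bools[, "Backup"] <- posture %in% c("Straight", "StraightLightBend") &
    disp & (ftab$axis_direction_25_10 < cfg$backup_axis_threshold)
  probs[, "Backup"] <- as.numeric(bools[, "Backup"])
  list(booleans = bools, action_probs = probs, posture_probs = pp,
       posture = posture, disp_status = disp)
}

#' Layer 2: resolve detector conflicts into a single state
#'
#' The printed hierarchical cascade: any action co-detected with Stop
#' becomes no-action, then with Roll, Backup, Bend, Crawl. Frames with
#' exactly one surviving detection keep it; frames with none (or with an
#' unresolved pair) are NoAction, to be filled by layers 3/4.
#'
#' @param booleans T x 7 logical matrix from [layer1_detect()].
#' @return Character vector of per-frame states (possibly "NoAction").
#' @export
hierarchy_regularize <- function(booleans) {
  b <- booleans
  for (a in c("Stop", "Roll", "Backup", "Bend", "Crawl")) {
    conflict <- b[, a] & rowSums(b) > 1L
    if (any(conflict)) b[conflict, ] <- FALSE
  }
  n_on <- rowSums(b)
  out <- rep("NoAction", nrow(b))
  one <- which(n_on == 1L)
  if (length(one)) out[one] <- colnames(b)[max.col(b[one, , drop = FALSE])]
  out
}

#' Regularize postural probabilities into one posture per frame
#'
#' Sequential rule in the order Ball, Curl, Bend, StraightLightBend,
#' Straight, using the classifier probabilities as criterion; ties go to
#' the earlier state in the order.
#'
#' @param posture_probs T x 5 matrix with columns in [posture_states()]
#'   order.
#' @return Factor of posture states.
#' @export
posture_regularize <- function(posture_probs) {
  stopifnot(ncol(posture_probs) == 5L)
  idx <- max.col(posture_probs, ties.method = "first")
  factor(posture_states()[idx], levels = posture_states())
}

layer34_design <- function(X, prior_states, prior_probs, cfg) {
  st <- factor(prior_states, levels = c(action_states(), "NoAction"))
  onehot <- stats::model.matrix(~ st - 1)
  colnames(onehot) <- paste0("state_", levels(st))
  sp <- smooth_prob_matrix(prior_probs, cfg$prob_smooth_window)
  colnames(sp) <- paste0("p_", colnames(prior_probs))
  cbind(X, onehot, sp)
}

#' Layers 3/4: definite per-frame classification
#'
#' Multiclass model on the frame features plus the layer-2 states and the
#' smoothed layer-1 probabilities. Every frame (including layer-2
#' NoAction frames) receives one of the seven actions.
#'
#' @param ftab Feature table.
#' @param prior_states Layer-2 state vector.
#' @param prior_probs Layer-1 probability matrix.
#' @param models A `trained_models`.
#' @param design Precomputed design matrix (internal fast path).
#' @return Character vector of per-frame actions (no NoAction).
#' @export
layer34_classify <- function(ftab, prior_states, prior_probs, models,
                             design = NULL) {
  if (is.null(design)) {
    X <- prepare_frame_features(ftab, models$cfg)[, models$feat_names, drop = FALSE]
    design <- layer34_design(X, prior_states, prior_probs, models$cfg)
  }
  as.character(stats::predict(models$layer34, design))
}

layer34_probs <- function(ftab, prior_states, prior_probs, models,
                          design = NULL) {
  if (is.null(design)) {
    X <- prepare_frame_features(ftab, models$cfg)[, models$feat_names, drop = FALSE]
    design <- layer34_design(X, prior_states, prior_probs, models$cfg)
  }
  stats::predict(models$layer34, design, type = "prob")
}

#' Correct singular one-frame events
#'
#' The printed pattern corrections for actions separated by one time
#' point: `i -> j -> i` becomes `i -> i -> i` and `i -> j -> k` becomes
#' `i -> k -> k`. Idempotent; never creates new one-frame interlopers.
#'
#' @param states Per-frame action states.
#' @return Corrected state vector.
#' @export
regularize_singular <- function(states) {
  states <- as.character(states)
  repeat {
    r <- rle(states)
    n <- length(r$values)
    if (n < 3L) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    singles <- which(r$lengths == 1L)
    singles <- singles[singles > 1L & singles < n]
    if (!length(singles)) break
    j <- singles[1L]
    pos <- starts[j]
    if (r$values[j - 1L] == r$values[j + 1L]) {
      states[pos] <- r$values[j - 1L]
    } else {
      states[pos] <- r$values[j + 1L]
    }
  }
  states
}

#' Event-level aggregated features
#'
#' The limited set of 14 per-event features used by the event-level layers
#' and the detection-quality heuristic: duration, frame count, length
#' ratio and relative length, minimal and mean S, mean per-body-length
#' speed, mean agitation, the three cluster-view features, mean bend
#' alignment, mean axis direction, and mean normalized head-tail distance.
#'
#' @param events Event table from [segment_events()] (with amplitudes).
#' @param ftab The feature table the events index into.
#' @return Data frame with one row per event.
#' @export
event_features <- function(events, ftab) {
  l_track <- mean(ftab$l, na.rm = TRUE)
  g <- function(ch, i, f = mean) {
    v <- ftab[[ch]][(events$start[i] + 1L):events$end[i]]
    v <- v[is.finite(v)]
    if (!length(v)) 0 else f(v)
  }
  out <- data.frame(
    duration = events$duration, n_frames = events$n_frames,
    l_ratio = events$l_min / events$l_max,
    l_rel = events$l_mean / l_track,
    S_min = ifelse(is.finite(events$S_min), events$S_min, 1),
    S_mean = vapply(seq_len(nrow(events)), function(i) g("S", i), numeric(1)),
    v_mean_bl = events$v_mean / l_track,
    v_a_mean = vapply(seq_len(nrow(events)), function(i) g("v_a", i), numeric(1)),
    x1_mean = vapply(seq_len(nrow(events)), function(i) g("x1_frame", i), numeric(1)),
    x3_mean = vapply(seq_len(nrow(events)), function(i) g("x3_frame", i), numeric(1)),
    x4_mean = vapply(seq_len(nrow(events)), function(i) g("x4_frame", i), numeric(1)),
    beta_mean = vapply(seq_len(nrow(events)), function(i) g("beta_15_5", i), numeric(1)),
    axis_dir_mean = vapply(seq_len(nrow(events)), function(i)
      g("axis_direction_25_10", i), numeric(1)),
    ht_norm_mean = vapply(seq_len(nrow(events)), function(i)
      g("dist_head_tail", i), numeric(1)) / l_track)
  out[] <- lapply(out, function(v) { v[!is.finite(v)] <- 0; v })
  out
}

#' Hunch-specific event correction
#'
#' Re-examines detected Hunch events with the event-level classifier
#' trained to differentiate head retraction from other quick motions
#' (using the length statistics over the event); rejected events are
#' reassigned to the strongest alternative from the frame probabilities.
#'
#' @param events Event table.
#' @param ftab Feature table.
#' @param models A `trained_models`.
#' @param frame_probs Optional T x 7 layer-3/4 probability matrix used to
#'   pick the alternative label.
#' @return The corrected event table.
#' @export
correct_hunches <- function(events, ftab, models, frame_probs = NULL) {
  if (nrow(events) == 0L) return(events)
  hz <- which(events$action == "Hunch")
  if (!length(hz)) return(events)
  if (is.null(models$hunch)) {
    warning("hunch-correction model untrained; events passed through")
    return(events)
  }
  if (identical(models$hunch, "keep-all")) return(events)
  ef <- event_features(events[hz, , drop = FALSE], ftab)
  keep <- stats::predict(models$hunch, ef) == "TRUE"
  for (k in which(!keep)) {
    i <- hz[k]
    alt <- "Small"
    if (!is.null(frame_probs)) {
      p <- colMeans(frame_probs[(events$start[i] + 1L):events$end[i], , drop = FALSE])
      p["Hunch"] <- -Inf
      alt <- names(p)[which.max(p)]
    }
    events$action[i] <- alt
  }
  events
}

#' Merge too-short Stop and Backup events
#'
#' Stops and Back-ups lasting less than 2 time points are transformed
#' into the closest action: the temporal neighbor with the longer
#' duration, ties going to the preceding neighbor.
#'
#' @param events Event table.
#' @param min_frames Frame threshold (default 2).
#' @return Corrected event table (adjacent equal actions merged).
#' @export
correct_short_events <- function(events, min_frames = 2L) {
  if (nrow(events) == 0L) return(events)
  for (i in seq_len(nrow(events))) {
    if (events$action[i] %in% c("Stop", "Backup") &&
        events$n_frames[i] < min_frames) {
      prev <- if (i > 1L) events$duration[i - 1L] else -Inf
      nxt <- if (i < nrow(events)) events$duration[i + 1L] else -Inf
      if (is.infinite(prev) && is.infinite(nxt)) next
      events$action[i] <- if (prev >= nxt) events$action[i - 1L]
                          else events$action[i + 1L]
    }
  }
  merge_events(events)
}

merge_events <- function(events) {
  if (nrow(events) < 2L) return(events)
  keep <- c(TRUE, events$action[-1L] != events$action[-nrow(events)])
  grp <- cumsum(keep)
  out <- events[keep, , drop = FALSE]
  for (g in unique(grp[duplicated(grp)])) {
    rows <- which(grp == g)
    i <- which(keep)[g]
    j <- match(g, grp[keep])
    out$end[j] <- events$end[max(rows)]
    out$t_end[j] <- events$t_end[max(rows)]
    out$duration[j] <- out$t_end[j] - out$t_start[j]
    out$n_frames[j] <- sum(events$n_frames[rows])
    if ("l_min" %in% names(events)) {
      out$l_min[j] <- min(events$l_min[rows])
      out$l_max[j] <- max(events$l_max[rows])
      out$l_mean[j] <- sum(events$l_mean[rows] * events$n_frames[rows]) /
        out$n_frames[j]
      out$lM_min[j] <- min(events$lM_min[rows])
      out$lM_max[j] <- max(events$lM_max[rows])
      out$S_min[j] <- min(events$S_min[rows])
      out$v_mean[j] <- sum(events$v_mean[rows] * events$n_frames[rows]) /
        out$n_frames[j]
    }
  }
  rownames(out) <- NULL
  out
}

events_to_states <- function(events, n) {
  st <- character(n)
  for (i in seq_len(nrow(events))) st[(events$start[i] + 1L):events$end[i]] <- events$action[i]
  st
}

#' Layer 5: event-level finalization
#'
#' Each event's duration-aggregated features go to the tree-ensemble and
#' max-margin finalizers; agreement fixes the label, disagreement is
#' resolved by the higher calibrated probability. Frames are relabeled
#' accordingly; the final ethogram contains no NoAction.
#'
#' @param events Event table.
#' @param ftab Feature table.
#' @param models A `trained_models`.
#' @return Relabeled event table.
#' @export
layer5_finalize <- function(events, ftab, models) {
  if (nrow(events) == 0L || is.null(models$layer5_rf)) return(events)
  ef <- event_features(events, ftab)
  p_rf <- stats::predict(models$layer5_rf, ef, type = "prob")
  pred_svm <- stats::predict(models$layer5_svm, as.matrix(ef), probability = TRUE)
  p_svm <- attr(pred_svm, "probabilities")
  lab_rf <- colnames(p_rf)[max.col(p_rf, ties.method = "first")]
  lab_svm <- colnames(p_svm)[max.col(p_svm, ties.method = "first")]
  out <- ifelse(lab_rf == lab_svm, lab_rf,
                ifelse(apply(p_rf, 1L, max) >= apply(p_svm, 1L, max),
                       lab_rf, lab_svm))
  events$action <- out
  merge_events(events)
}

#' Legacy amplitude-threshold flags
#'
#' Links the generalized action definitions back to the older
#' threshold-based ones: a Hunch is legacy-positive iff its length ratio
#' `l_min/l_max <= 0.8`, a Bend iff its minimal S `<= 0.81`.
#'
#' @param events Event table with amplitude summaries.
#' @param cfg A [classifier_config()].
#' @return `events` with a logical `legacy` column (NA for other actions).
#' @export
legacy_filter <- function(events, cfg = classifier_config()) {
  events$legacy <- NA
  h <- events$action == "Hunch"
  events$legacy[h] <- (events$l_min[h] / events$l_max[h]) <= cfg$legacy_dl
  b <- events$action == "Bend"
  events$legacy[b] <- events$S_min[b] <= cfg$legacy_S
  events
}

# ---- end-to-end prediction ------------------------------------------------

#' Classify one track into a final ethogram
#'
#' Runs the full layer stack: layer-1 detection, hierarchy
#' regularization, layer-3/4 classification, singular-event
#' regularization, event segmentation, hunch correction, short-event
#' correction, and layer-5 finalization.
#'
#' @param track An oriented `larva_track`.
#' @param models A `trained_models`.
#' @param fcfg A [feature_config()].
#' @param ftab Optional precomputed feature table.
#' @return An [ethogram()] (with an `events` table carrying amplitudes).
#' @export
classify_track <- function(track, models, fcfg = feature_config(), ftab = NULL) {
  if (is.null(ftab)) ftab <- compute_features(track, fcfg)
  times <- attr(ftab, "times")
  l1 <- layer1_detect(ftab, models)
  l2 <- hierarchy_regularize(l1$booleans)
  X <- prepare_frame_features(ftab, models$cfg)[, models$feat_names, drop = FALSE]
  design <- layer34_design(X, l2, l1$action_probs, models$cfg)
  probs34 <- layer34_probs(ftab, NULL, NULL, models, design = design)
  st <- colnames(probs34)[max.col(probs34, ties.method = "first")]
  st <- regularize_singular(st)
  ev <- segment_events(st, times, ftab)
  ev <- correct_hunches(ev, ftab, models, frame_probs = probs34)
  ev <- merge_events(ev)
  ev <- correct_short_events(ev, models$cfg$min_event_frames)
  ev <- layer5_finalize(ev, ftab, models)
  st <- events_to_states(ev, length(times))
  ev <- segment_events(st, times, ftab)
  ethogram(track$track_id, times, st, events = ev)
}

#' Classify every track of a set
#'
#' @param ts A `track_set` (tracks should be oriented).
#' @param models A `trained_models`.
#' @param fcfg A [feature_config()].
#' @return An `ethogram_set`.
#' @export
classify_tracks <- function(ts, models, fcfg = feature_config()) {
  ethos <- lapply(ts$tracks, classify_track, models = models, fcfg = fcfg)
  ethogram_set(ts$line_id, unname(ethos), ts$stimulus)
}

# ---- quality heuristic ----------------------------------------------------

#' Detection-quality heuristic
#'
#' Predicts the pipeline's own event labels from the 14 event-averaged
#' features with cross-validated k-nearest-neighbour and random-forest
#' classifiers; high per-action accuracy indicates a stable,
#' non-overfitted behavioral representation.
#'
#' @param event_feats Event-feature data frame ([event_features()]),
#'   possibly pooled over larvae.
#' @param labels Pipeline event labels.
#' @param seed Integer seed.
#' @param k Neighbours for kNN (classes with fewer events are excluded).
#' @return Data frame: action, n_events, accuracy_knn, accuracy_rf.
#' @export
quality_heuristic <- function(event_feats, labels, seed = 1L, k = 5L) {
  labels <- as.character(labels)
  tab <- table(labels)
  keep_classes <- names(tab)[tab >= k]
  excluded <- setdiff(names(tab), keep_classes)
  if (length(excluded)) {
    message("excluded class(es) with fewer than ", k, " events: ",
            paste(excluded, collapse = ", "))
  }
  sel <- labels %in% keep_classes
  X <- scale(as.matrix(event_feats[sel, , drop = FALSE]))
  X[!is.finite(X)] <- 0
  y <- factor(labels[sel])
  set.seed(seed)
  knn_pred <- class::knn.cv(X, y, k = k)
  rf <- rf_fit(as.data.frame(X), y, 200L, seed)
  rf_pred <- rf$predicted # out-of-bag cross-validated
  res <- do.call(rbind, lapply(levels(y), function(a) {
    i <- y == a
    data.frame(action = a, n_events = sum(i),
               accuracy_knn = mean(knn_pred[i] == a),
               accuracy_rf = mean(rf_pred[i] == a))
  }))
  rownames(res) <- NULL
  res
}
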