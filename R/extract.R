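pop_sd <- function(x) {
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Extract the feature vector of one session
#'
#' Computes every manifest entry for one child-game session. Inertial
#' features are computed across the whole inertial stream irrespective of
#' the touch data (or, when `window` is shorter than the session, per
#' consecutive non-overlapping window and then averaged — the per-window
#' values for each feature reduced to their mean). Screen features are
#' per-gesture kinematics aggregated over the session's gestures plus
#' session-level count/timing features.
#'
#' Masking: a session with zero gestures has every screen entry `NA`; an
#' inertial stream with fewer than 2 samples has every inertial entry `NA`;
#' correlation entries are `NA` when an input axis is constant.
#'
#' @param session a validated `game_session`.
#' @param manifest a [feature_manifest()].
#' @param window optional window length in seconds for windowed inertial
#'   extraction; `NULL` (default) computes a single pass over the stream.
#' @param tap_path_epsilon forwarded to [segment_gestures()].
#' @return a named numeric vector aligned to the manifest (class
#'   `feature_vector`), with `child_id` and `game` attributes.
#' @export
extract_features <- function(session, manifest = feature_manifest(),
                             window = NULL, tap_path_epsilon = 10) {
  stopifnot(inherits(session, "game_session"))
  inertial <- inertial_feature_values(session, window)
  screen <- screen_feature_values(session, tap_path_epsilon)

  kind <- manifest$kind; signal <- manifest$signal; axis <- manifest$axis
  stat <- manifest$stat; quantity <- manifest$quantity
  aggregate <- manifest$aggregate
  values <- vapply(seq_len(nrow(manifest)), function(i) {
    switch(kind[i],
      axis_stat = inertial$axis[[signal[i]]][[axis[i]]][[stat[i]]],
      magnitude_stat = inertial$mag[[signal[i]]][[stat[i]]],
      axis_corr = inertial$corr[[signal[i]]][[axis[i]]],
      cross = inertial$cross[[stat[i]]],
      gesture_agg = screen$agg[[quantity[i]]][[aggregate[i]]],
      session = screen$session[[stat[i]]],
      stop("unknown manifest kind: ", kind[i]))
  }, numeric(1))
  names(values) <- manifest$name
  structure(values, class = "feature_vector",
            child_id = session$child_id, game = session$game,
            manifest_version = attr(manifest, "version"))
}

SIGNAL_COLS <- list(accel = c("ax", "ay", "az"),
                    rotation = c("gx", "gy", "gz"),
                    attitude = c("ox", "oy", "oz"))

inertial_feature_values <- function(session, window = NULL) {
  it <- session$inertial
  dur <- session$duration
  if (is.null(window) || window >= dur) {
    return(inertial_block(it, dur))
  }
  starts <- seq(0, dur - 1e-9, by = window)
  blocks <- lapply(starts, function(s0) {
    w <- it[it$t >= s0 & it$t < min(s0 + window, dur + 1e-9), , drop = FALSE]
    if (nrow(w) < 2) return(NULL)
    inertial_block(w, min(window, dur - s0))
  })
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  if (!length(blocks)) return(inertial_block(it[0, ], dur))
  average_blocks(blocks)
}

inertial_block <- function(it, duration) {
  empty <- nrow(it) < 2
  na15 <- stats::setNames(as.list(rep(NA_real_, length(AXIS_STATS))),
                          names(AXIS_STATS))
  out <- list(axis = list(), mag = list(), corr = list(), cross = list())
  mags <- list()
  for (sig in names(SIGNAL_COLS)) {
    cols <- SIGNAL_COLS[[sig]]
    out$axis[[sig]] <- list()
    for (j in 1:3) {
      ax <- c("x", "y", "z")[j]
      out$axis[[sig]][[ax]] <- if (empty) na15 else
        as.list(axis_stats(it[[cols[j]]], duration))
    }
    if (empty) {
      out$mag[[sig]] <- stats::setNames(
        as.list(rep(NA_real_, length(MAG_STATS))), names(MAG_STATS))
      out$corr[[sig]] <- list("0_1" = NA_real_, "0_2" = NA_real_,
                              "1_2" = NA_real_)
    } else {
      m <- magnitude_series(as.matrix(it[cols]))
      mags[[sig]] <- m
      out$mag[[sig]] <- list(mean = mean(m), std = pop_sd(m),
                             rms = sqrt(mean(m^2)), min = min(m), max = max(m))
      out$corr[[sig]] <- list(
        "0_1" = pairwise_corr(it[[cols[1]]], it[[cols[2]]]),
        "0_2" = pairwise_corr(it[[cols[1]]], it[[cols[3]]]),
        "1_2" = pairwise_corr(it[[cols[2]]], it[[cols[3]]]))
    }
  }
  if (empty) {
    out$cross <- list(accel_rotation_corr = NA_real_,
                      accel_dattitude_corr = NA_real_,
                      rotation_dattitude_corr = NA_real_,
                      accel_rotation_ratio = NA_real_,
                      sample_count = NA_real_)
  } else {
    datt <- magnitude_series(diff(as.matrix(it[SIGNAL_COLS$attitude])))
    out$cross <- list(
      accel_rotation_corr = pairwise_corr(mags$accel, mags$rotation),
      accel_dattitude_corr = pairwise_corr(mags$accel[-1], datt),
      rotation_dattitude_corr = pairwise_corr(mags$rotation[-1], datt),
      accel_rotation_ratio = if (mean(mags$rotation) > 0)
        mean(mags$accel) / mean(mags$rotation) else NA_real_,
      sample_count = as.numeric(nrow(it)))
  }
  out
}

# Elementwise mean of per-window inertial blocks (feature values for each
# window reduced to their mean; windows where a value is undefined are
# skipped for that value).
average_blocks <- function(blocks) {
  tmpl <- blocks[[1]]
  avg_leaf <- function(path) {
    vals <- vapply(blocks, function(b) {
      v <- b
      for (p in path) v <- v[[p]]
      v
    }, numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }
  rec <- function(node, path) {
    if (is.list(node)) {
      stats::setNames(lapply(names(node), function(k) rec(node[[k]], c(path, k))),
                      names(node))
    } else {
      avg_leaf(path)
    }
  }
  rec(tmpl, character(0))
}

screen_feature_values <- function(session, tap_path_epsilon = 10) {
  gestures <- segment_gestures(session, tap_path_epsilon)
  n <- length(gestures)
  qnames <- names(GESTURE_QUANTITIES)
  aggs <- names(GESTURE_AGGREGATES)
  if (!n) {
    na_aggs <- stats::setNames(as.list(rep(NA_real_, length(aggs))), aggs)
    return(list(
      agg = stats::setNames(rep(list(na_aggs), length(qnames)), qnames),
      session = stats::setNames(
        as.list(rep(NA_real_, nrow(SESSION_FEATURES))), SESSION_FEATURES$key)))
  }
  kin <- t(vapply(gestures, gesture_kinematics, numeric(13)))

  agg <- lapply(qnames, function(q) {
    v <- kin[, q]
    list(mean = mean(v), std = pop_sd(v), min = min(v), max = max(v),
         median = stats::median(v), sum = sum(v))
  })
  names(agg) <- qnames

  t_start <- vapply(gestures, `[[`, numeric(1), "t_start")
  t_end <- vapply(gestures, `[[`, numeric(1), "t_end")
  n_pointers <- vapply(gestures, `[[`, numeric(1), "n_pointers")
  is_tap <- vapply(gestures, `[[`, logical(1), "is_tap")
  gaps <- if (n >= 2) t_start[-1] - t_end[-n] else numeric(0)
  dts <- unlist(lapply(gestures, function(g) {
    unlist(lapply(split(g$samples$t, g$samples$id), function(ts) {
      if (length(ts) >= 2) diff(ts) else numeric(0)
    }), use.names = FALSE)
  }), use.names = FALSE)
  dur <- session$duration

  sess <- list(
    gesture_count = n,
    tap_count = sum(is_tap),
    drag_count = sum(!is_tap & n_pointers == 1),
    multi_touch_count = sum(n_pointers >= 2),
    gestures_per_s = n / dur,
    taps_per_s = sum(is_tap) / dur,
    total_touch_time = sum(t_end - t_start),
    touch_time_fraction = sum(t_end - t_start) / dur,
    gap_mean = if (length(gaps)) mean(gaps) else NA_real_,
    gap_std = if (length(gaps)) pop_sd(gaps) else NA_real_,
    gap_min = if (length(gaps)) min(gaps) else NA_real_,
    gap_max = if (length(gaps)) max(gaps) else NA_real_,
    max_pointers = max(n_pointers),
    mean_pointers = mean(n_pointers),
    tap_fraction = mean(is_tap),
    first_touch_latency = t_start[1],
    total_path_length = sum(kin[, "path_length"]),
    total_area = sum(kin[, "area"]),
    mean_sampling_interval = if (length(dts)) mean(dts) else NA_real_,
    nonzero_area_count = sum(kin[, "area"] > 0))
  list(agg = agg, session = sess)
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> child %s, %s game: %d features (%d masked)\n",
              attr(x, "child_id"), attr(x, "game"), length(x),
              sum(is.na(x))))
  invisible(x)
}

#' Extract the feature matrix of a cohort of sessions
#'
#' @param sessions list of `game_session` objects.
#' @param manifest a [feature_manifest()].
#' @param window optional inertial window length (seconds).
#' @return a data frame with metadata columns `child_id`, `game`, `label`,
#'   `age_months`, `gender` followed by one column per manifest feature.
#' @export
extract_cohort <- function(sessions, manifest = feature_manifest(),
                           window = NULL) {
  stopifnot(length(sessions) > 0)
  rows <- lapply(sessions, function(s) {
    fv <- extract_features(s, manifest, window)
    meta <- data.frame(
      child_id = s$child_id, game = s$game,
      label = s$label %||% NA_character_,
      age_months = s$age_months %||% NA_integer_,
      gender = s$gender %||% NA_character_,
      stringsAsFactors = FALSE)
    cbind(meta, as.data.frame(as.list(unclass(fv)), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "manifest_version") <- attr(manifest, "version")
  out
}

#' Columns of a feature matrix that are manifest features
#' @param features a feature matrix from [extract_cohort()].
#' @param manifest the manifest it was built against.
#' @return character vector of feature column names present.
#' @export
feature_columns <- function(features, manifest = feature_manifest()) {
  intersect(manifest$name, colnames(features))
}
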