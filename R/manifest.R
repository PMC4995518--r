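# The feature catalogue: an ordered manifest of 262 named features computed
# per child per game. 164 come from the inertial streams (accelerometer,
# gyroscope rotation rate, attitude), 98 from the touch screen (per-gesture
# kinematics aggregated over gestures, plus session-level counts/timing).

AXIS_STATS <- c(mean = "Mean", std = "StdDev", rms = "RMS", min = "Min",
                max = "Max", range = "Range", median = "Median", iqr = "IQR",
                skewness = "Skewness", kurtosis = "Kurtosis",
                zero_cross_count = "ZeroCrossing",
                zero_cross_rate = "ZeroCrossRate", mean_abs = "MeanAbs",
                energy = "Energy", mean_abs_diff = "MeanAbsDiff")

MAG_STATS <- c(mean = "Mean", std = "StdDev", rms = "RMS",
               min = "Min", max = "Max")

SIGNALS <- c(accel = "Accel", rotation = "Rotation", attitude = "Attitude")

GESTURE_QUANTITIES <- c(
  duration = "GestureDuration", path_length = "GesturePathLength",
  mean_speed = "GestureSpeed", max_speed = "GestureMaxSpeed",
  mean_accel = "GestureAccel", max_accel = "GestureMaxAccel",
  area = "GestArea", height = "GesturesHeight", lateral = "GesturesLateral",
  x_extent = "GestureExtentX", y_extent = "GestureExtentY",
  straightness = "GestureStraightness", n_samples = "GestureSampleCount")

GESTURE_AGGREGATES <- c(mean = "Mean", std = "StdDev", min = "Min",
                        max = "Max", median = "Median", sum = "Sum")

# How each per-gesture quantity scales when screen coordinates are scaled
# by k: value scales by k^dim.
QUANTITY_LENGTH_DIM <- c(
  duration = 0, path_length = 1, mean_speed = 1, max_speed = 1,
  mean_accel = 1, max_accel = 1, area = 2, height = 1, lateral = 1,
  x_extent = 1, y_extent = 1, straightness = 0, n_samples = 0)

SESSION_FEATURES <- data.frame(
  key = c("gesture_count", "tap_count", "drag_count", "multi_touch_count",
          "gestures_per_s", "taps_per_s", "total_touch_time",
          "touch_time_fraction", "gap_mean", "gap_std", "gap_min", "gap_max",
          "max_pointers", "mean_pointers", "tap_fraction",
          "first_touch_latency", "total_path_length", "total_area",
          "mean_sampling_interval", "nonzero_area_count"),
  name = c("GestureCount", "TapCount", "DragCount", "MultiTouchCount",
           "GesturesPerSecond", "TapsPerSecond", "TotalTouchTime",
           "TouchTimeFraction", "InterGestureGapMean", "InterGestureGapStdDev",
           "InterGestureGapMin", "InterGestureGapMax",
           "MaxSimultaneousPointers", "MeanPointersPerGesture", "TapFraction",
           "FirstTouchLatency", "TotalPathLength", "TotalGestureArea",
           "MeanSamplingInterval", "NonZeroAreaGestureCount"),
  length_dim = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 2, 0, 0),
  stringsAsFactors = FALSE)

# Names printed in the field's feature tables that deviate from the
# systematic <Quantity><Aggregate> pattern.
SCREEN_NAME_OVERRIDES <- c(
  GestureSpeedMean = "Velocity",
  GestAreaMean = "AvgGestArea",
  GesturesHeightMean = "AvgGesturesHeight")

# Historic aliases: alternative spellings of catalogue features.
FEATURE_ALIASES <- c(AccelerationRMS_y = "AccelRMS_y")

magnitude_prefix <- function(signal, stat) {
  base <- switch(signal, accel = "AccelerationMagnitude",
                 rotation = "RotationMagnitude",
                 attitude = "AttitudeMagnitude")
  if (signal == "rotation" && stat == "mean") return("RotationMeanMagnitude")
  paste0(base, MAG_STATS[[stat]])
}

#' The default feature manifest
#'
#' Builds the ordered 262-entry feature catalogue: for each inertial signal
#' (acceleration, rotation rate, attitude) 15 statistics per axis, 5
#' magnitude statistics and 3 axis-pair Pearson correlations (3 x 53 = 159),
#' plus 5 cross-signal features; then 13 per-gesture kinematic quantities
#' aggregated over gestures by 6 aggregates (78) plus 20 session-level
#' touch features. Feature names follow the catalogue's established
#' conventions (e.g. `AccelZeroCrossing_x`, `RotationCorrelation_1_2`,
#' `Velocity`, `AvgGestArea`, `GestureDurationMin`).
#'
#' @return a data frame of class `feature_manifest` with one row per
#'   feature: `name`, `source` (`"inertial"`/`"screen"`), `kind`, `signal`,
#'   `axis`, `stat`, `quantity`, `aggregate`, `length_dim` (power of the
#'   screen-length unit in the feature's dimension), and a `version`
#'   attribute.
#' @export
feature_manifest <- function() {
  cached <- get0("default_manifest", envir = .manifest_cache)
  if (!is.null(cached)) return(cached)
  m <- build_manifest()
  assign("default_manifest", m, envir = .manifest_cache)
  m
}

.manifest_cache <- new.env(parent = emptyenv())

build_manifest <- function() {
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)

  for (sig in names(SIGNALS)) {
    for (ax in c("x", "y", "z")) {
      for (st in names(AXIS_STATS)) {
        add(name = paste0(SIGNALS[[sig]], AXIS_STATS[[st]], "_", ax),
            source = "inertial", kind = "axis_stat", signal = sig, axis = ax,
            stat = st, quantity = NA, aggregate = NA, length_dim = 0)
      }
    }
    for (st in names(MAG_STATS)) {
      add(name = magnitude_prefix(sig, st), source = "inertial",
          kind = "magnitude_stat", signal = sig, axis = NA, stat = st,
          quantity = NA, aggregate = NA, length_dim = 0)
    }
    for (pair in c("0_1", "0_2", "1_2")) {
      add(name = paste0(SIGNALS[[sig]], "Correlation_", pair),
          source = "inertial", kind = "axis_corr", signal = sig, axis = pair,
          stat = NA, quantity = NA, aggregate = NA, length_dim = 0)
    }
  }
  cross <- c(accel_rotation_corr = "CrossCorrAccelRotationMagnitude",
             accel_dattitude_corr = "CrossCorrAccelAttitudeDiffMagnitude",
             rotation_dattitude_corr = "CrossCorrRotationAttitudeDiffMagnitude",
             accel_rotation_ratio = "AccelRotationMagnitudeRatio",
             sample_count = "InertialSampleCount")
  for (k in names(cross)) {
    add(name = cross[[k]], source = "inertial", kind = "cross", signal = NA,
        axis = NA, stat = k, quantity = NA, aggregate = NA, length_dim = 0)
  }

  for (q in names(GESTURE_QUANTITIES)) {
    for (agg in names(GESTURE_AGGREGATES)) {
      systematic <- paste0(GESTURE_QUANTITIES[[q]], GESTURE_AGGREGATES[[agg]])
      nm <- SCREEN_NAME_OVERRIDES[systematic]
      add(name = if (is.na(nm)) systematic else unname(nm),
          source = "screen", kind = "gesture_agg", signal = NA, axis = NA,
          stat = NA, quantity = q, aggregate = agg,
          length_dim = QUANTITY_LENGTH_DIM[[q]])
    }
  }
  for (i in seq_len(nrow(SESSION_FEATURES))) {
    add(name = SESSION_FEATURES$name[i], source = "screen", kind = "session",
        signal = NA, axis = NA, stat = SESSION_FEATURES$key[i], quantity = NA,
        aggregate = NA, length_dim = SESSION_FEATURES$length_dim[i])
  }

  m <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(m$name))
  attr(m, "version") <- "1.0"
  class(m) <- c("feature_manifest", "data.frame")
  m
}

#' Resolve a feature name, honouring catalogue aliases
#'
#' @param name character vector of feature names (canonical or alias).
#' @param manifest a [feature_manifest()].
#' @return canonical names; errors on names absent from the catalogue.
#' @export
resolve_feature_name <- function(name, manifest = feature_manifest()) {
  out <- ifelse(name %in% names(FEATURE_ALIASES),
                FEATURE_ALIASES[name], name)
  bad <- setdiff(out, manifest$name)
  if (length(bad)) {
    stop("unknown feature name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}

#' @export
print.feature_manifest <- function(x, ...) {
  cat(sprintf("<feature_manifest> v%s: %d features (%d inertial, %d screen)\n",
              attr(x, "version"), nrow(x), sum(x$source == "inertial"),
              sum(x$source == "screen")))
  invisible(x)
}

#' Write / read a manifest as versioned JSON
#'
#' @param manifest a `feature_manifest`.
#' @param path output file.
#' @return `path` (write) or a `feature_manifest` (read).
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(
    list(version = attr(manifest, "version"),
         features = as.data.frame(manifest)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  doc <- jsonlite::fromJSON(path)
  m <- doc$features
  attr(m, "version") <- doc$version
  class(m) <- c("feature_manifest", "data.frame")
  m
}
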