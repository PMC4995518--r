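small_spec <- function(duration = 60, games = "creativity", n1 = 2, n2 = 2) {
  cohort_spec(n_asd = n1, n_control = n2, duration = duration, games = games)
}

test_child <- function(seed = 1, ...) {
  overrides <- list(...)
  ch <- list(child_id = "t1", label = "control", age_months = 50L,
             gender = "f", seed = seed,
             impact_force = 1.0, lateral_force_share = 0.25,
             gesture_speed = 300, gesture_area_scale = 1,
             gesture_height_mean = 0.35, gesture_height_sd = 0.08,
             tap_duration_floor = 0.08,
             coupling = diag(3))
  ch[names(overrides)] <- overrides
  ch
}

test_that("the default cohort has the study's size, split and demographics", {
  co <- sample_cohort(cohort_spec(), effect_profile(), seed = 5)
  expect_equal(nrow(co), 82)
  expect_equal(sum(co$label == "asd"), 37)
  expect_equal(sum(co$label == "control"), 45)
  expect_equal(sum(co$gender == "f" & co$label == "asd"), 12)
  expect_equal(sum(co$gender == "f" & co$label == "control"), 13)
  expect_true(all(co$age_months >= 36 & co$age_months <= 83))
  # reproducible and seed-sensitive
  co2 <- sample_cohort(cohort_spec(), effect_profile(), seed = 5)
  expect_identical(as.data.frame(co), as.data.frame(co2))
  co3 <- sample_cohort(cohort_spec(), effect_profile(), seed = 6)
  expect_false(identical(co$impact_force, co3$impact_force))
})

test_that("a zero effect multiplier collapses both groups onto the control distribution", {
  p0 <- effect_profile(m = 0)
  for (param in motorsig:::SCALAR_PARAMS) {
    expect_equal(motorsig:::group_mean(p0, param, "asd"),
                 motorsig:::group_mean(p0, param, "control"))
  }
  expect_equal(motorsig:::group_coupling(p0, "asd"),
               motorsig:::group_coupling(p0, "control"))
  # and at m = 1 the stated group means are recovered
  p1 <- effect_profile(m = 1)
  expect_equal(motorsig:::group_mean(p1, "impact_force", "asd"), 1.6)
  expect_equal(motorsig:::group_mean(p1, "tap_duration_floor", "control"), 0.08)
})

test_that("simulated sessions satisfy the session invariants and pipeline closure", {
  spec <- small_spec()
  co <- sample_cohort(spec, effect_profile(), seed = 3)
  for (i in c(1, 3)) {
    s <- simulate_session(motorsig:::child_profile(co, i), "creativity", spec)
    expect_silent(validate_session(s))
    expect_true(all(s$touch$t <= s$duration))
    expect_true(!is.unsorted(s$inertial$t))
    # round-trip and partition closure
    s2 <- read_session(write_session(s, compress = TRUE))
    g <- segment_gestures(s2)
    expect_equal(sum(vapply(g, function(x) nrow(x$samples), numeric(1))),
                 nrow(s2$touch))
    # deterministic per child seed
    s3 <- simulate_session(motorsig:::child_profile(co, i), "creativity", spec)
    expect_identical(s3$touch, s$touch)
    expect_identical(s3$inertial, s$inertial)
  }
})

test_that("sharing gameplay emits tap-then-four-drag cycles at the expected rate", {
  spec <- small_spec(duration = 300, games = "sharing")
  co <- sample_cohort(spec, effect_profile(), seed = 9)
  s <- simulate_session(motorsig:::child_profile(co, 1), "sharing", spec)
  g <- segment_gestures(s)
  taps <- sum(vapply(g, `[[`, logical(1), "is_tap"))
  drags <- sum(!vapply(g, `[[`, logical(1), "is_tap"))
  expect_gte(taps, 300 / 20)           # at least one cycle per 20 s on average
  expect_gte(drags, 4 * (taps - 1))    # four distribution drags per full cycle
})

test_that("drag speeds track the child's speed parameter; doubling speed halves durations", {
  spec <- small_spec(duration = 120)
  drag_kin <- function(speed, seed = 77) {
    s <- simulate_session(test_child(seed, gesture_speed = speed),
                          "creativity", spec)
    g <- segment_gestures(s)
    g <- g[!vapply(g, `[[`, logical(1), "is_tap") &
             vapply(g, `[[`, numeric(1), "n_pointers") == 1]
    t(vapply(g, gesture_kinematics, numeric(13)))
  }
  k300 <- drag_kin(300)
  expect_equal(mean(k300[, "mean_speed"]), 300, tolerance = 0.1)
  k600 <- drag_kin(600)
  n <- min(nrow(k300), nrow(k600))
  # same seed, same underlying strokes (up to resampling): durations halve
  expect_equal(k600[1:n, "path_length"], k300[1:n, "path_length"],
               tolerance = 0.02)
  expect_equal(k600[1:n, "duration"], k300[1:n, "duration"] / 2,
               tolerance = 1e-8)
})

test_that("tap durations respect the child's floor", {
  spec <- small_spec(duration = 120)
  s <- simulate_session(test_child(5, tap_duration_floor = 0.07),
                        "creativity", spec)
  g <- segment_gestures(s)
  taps <- g[vapply(g, `[[`, logical(1), "is_tap")]
  durs <- vapply(taps, function(x) x$t_end - x$t_start, numeric(1))
  expect_gte(length(durs), 3)
  expect_true(all(durs >= 0.07))
})

test_that("a touchless session yields pure baseline noise with near-zero means", {
  spec <- small_spec(duration = 300)
  set.seed(31)
  it <- inertial_response(data.frame(t = numeric(0), id = integer(0),
                                     phase = character(0), x = numeric(0),
                                     y = numeric(0)),
                          test_child(), spec)
  expect_equal(nrow(it), 3001)
  for (col in c("ax", "ay", "az", "gx", "gy", "gz")) {
    expect_lt(abs(mean(it[[col]])), 0.01)
  }
})

test_that("doubling impact force increases the peak acceleration magnitude", {
  spec <- small_spec(duration = 60)
  s1 <- simulate_session(test_child(11, impact_force = 1), "creativity", spec)
  s2 <- simulate_session(test_child(11, impact_force = 2), "creativity", spec)
  m1 <- max(magnitude_series(as.matrix(s1$inertial[c("ax", "ay", "az")])))
  m2 <- max(magnitude_series(as.matrix(s2$inertial[c("ax", "ay", "az")])))
  expect_gt(m2, m1)
})

test_that("touches far from the device centre produce larger rotation impulses", {
  spec <- small_spec(duration = 10)
  ch <- test_child()
  rot_energy <- function(x, y) {
    touch <- touch_df(c(1, 1.1), 0L, c("began", "ended"), x, y)
    set.seed(55)
    it <- inertial_response(touch, ch, spec)
    sum(it$gx^2 + it$gy^2 + it$gz^2)
  }
  centre <- rot_energy(512, 384)
  corner <- rot_energy(1000, 740)
  expect_gt(corner, centre)
})

test_that("the calibrated generator recovers the encoded group differences", {
  rankings <- calibration_rankings()     # five seeds, n = 200 + 200
  for (f in names(MANIPULATED_FEATURES)) {
    rows <- lapply(rankings, function(r) r[r$feature == f, ])
    d_med <- median(vapply(rows, `[[`, numeric(1), "D"))
    expect_gte(d_med, 0.3)
    dirs <- vapply(rows, `[[`, character(1), "direction")
    expect_equal(unname(sort(table(dirs), decreasing = TRUE)[1] >= 3), TRUE)
    expect_equal(names(sort(table(dirs), decreasing = TRUE))[1],
                 unname(MANIPULATED_FEATURES[f]))
  }
})

test_that("the headline screen and inertial features rank inside the top 15", {
  ranking <- calibration_rankings()[[1]]
  for (f in c("AccelerationMagnitudeMax", "Velocity", "AvgGestArea",
              "GestureDurationMin", "GesturesHeightStdDev")) {
    expect_lte(ranking$rank[ranking$feature == f], 15)
  }
})

test_that("at zero effect the pipeline does not discriminate", {
  # pooled sample sized so the chance band is several null-SDs wide
  feats <- sim_cohort_features(30, 34, m = 0, seed = 404, duration = 180)
  rec <- run_cv(feats, feats$label,
                cv_config(k = 10, repetitions = 5, model = "rf",
                          n_trees = 200, base_seed = 8),
                child_id = feats$child_id)
  a <- auc(rec)
  expect_gte(a, 0.35); expect_lte(a, 0.65)
  # and no feature's KS distance escapes the small-sample null envelope
  alpha <- 1 - 0.99^(1 / 262)
  bound <- sqrt(-log(alpha / 2) / 2) * sqrt((30 + 34) / (30 * 34))
  ranking <- rank_features(feats, top_k = 1)
  expect_lt(ranking$D[1], bound)
})

test_that("discrimination grows monotonically with the effect multiplier", {
  med <- monotone_auc_medians()          # m = 0, 0.5, 1, 2
  expect_true(all(diff(med) >= 0))
  expect_lt(med[1], 0.7)
  expect_gt(med[4], 0.9)
})
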