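test_that("feature vectors align with the manifest in length and order", {
  m <- feature_manifest()
  s <- random_session(5, duration = 30)
  fv <- extract_features(s, m)
  expect_length(fv, nrow(m))
  expect_identical(names(unclass(fv)), m$name)
})

test_that("manifest names map to their published definitions", {
  n <- 21
  it <- inertial_df(seq(0, 2, length.out = n),
                    ax = sin(1:n), ay = cos(1:n) * 2, az = rep(1, n),
                    gx = (1:n) / n, gy = sin(1:n / 2), gz = cos(1:n / 3),
                    ox = rep(0.1, n) + (1:n) / 100, oy = sin(1:n) / 10,
                    oz = rep(0, n))
  touch <- rbind(tap_touch(0.2, 100, 300, dur = 0.05),
                 drag_touch(1, 200, 100, 400, 100, dur = 0.5, n = 11))
  s <- game_session("c", "creativity", touch = touch, inertial = it,
                    duration = 3)
  fv <- extract_features(s)

  expect_equal(fv[["AccelRMS_y"]], sqrt(mean(it$ay^2)))
  expect_equal(fv[["AccelZeroCrossing_x"]], zero_crossings(it$ax))
  expect_equal(fv[["RotationMin_z"]], min(it$gz))
  expect_equal(fv[["AttitudeMean_y"]], mean(it$oy))
  expect_equal(fv[["RotationMeanMagnitude"]],
               mean(sqrt(it$gx^2 + it$gy^2 + it$gz^2)))
  expect_equal(fv[["AccelerationMagnitudeMax"]],
               max(sqrt(it$ax^2 + it$ay^2 + it$az^2)))
  expect_equal(fv[["RotationCorrelation_1_2"]], cor(it$gy, it$gz))
  expect_equal(fv[["AttitudeZeroCrossRate_x"]], zero_crossings(it$ox) / 3)

  # screen: two gestures with speeds 0 (tap) and 400 pts/s (drag)
  expect_equal(fv[["Velocity"]], mean(c(0, 400)))
  expect_equal(fv[["GestureDurationMin"]], 0.05)
  expect_equal(fv[["GesturesHeightMax"]], 300)   # drag centroid x = 300
  expect_equal(fv[["AvgGesturesHeight"]], mean(c(100, 300)))
  expect_equal(fv[["GestureCount"]], 2)
  expect_equal(fv[["TapCount"]], 1)
  expect_equal(fv[["FirstTouchLatency"]], 0.2)
  expect_equal(fv[["TotalPathLength"]], 200)
})

test_that("an identically-zero inertial stream gives zero magnitudes", {
  it <- inertial_df(seq(0, 5, by = 0.1))
  s <- game_session("c", "creativity", inertial = it, duration = 5)
  fv <- extract_features(s)
  expect_equal(fv[["AccelerationMagnitudeMax"]], 0)
  expect_equal(fv[["RotationMeanMagnitude"]], 0)
  expect_true(is.na(fv[["RotationCorrelation_1_2"]]))  # constant axes
})

test_that("masking: no gestures masks all screen entries, no inertial masks inertial", {
  m <- feature_manifest()
  it <- inertial_df(seq(0, 5, by = 0.1), ax = rnorm(51))
  s <- game_session("c", "creativity", inertial = it, duration = 5)
  fv <- extract_features(s)
  expect_true(all(is.na(fv[m$name[m$source == "screen"]])))
  expect_false(all(is.na(fv[m$name[m$source == "inertial"]])))

  s2 <- game_session("c", "creativity", touch = tap_touch(1, 50, 50),
                     duration = 5)
  fv2 <- extract_features(s2)
  expect_true(all(is.na(fv2[m$name[m$source == "inertial"]])))
  expect_equal(fv2[["GestureCount"]], 1)
})

test_that("screen features scale with coordinate dimension; inertial are untouched", {
  m <- feature_manifest()
  k <- 2.5
  for (seed in c(11, 12)) {
    s <- random_session(seed, duration = 40)
    s_scaled <- s
    s_scaled$touch$x <- s$touch$x * k
    s_scaled$touch$y <- s$touch$y * k
    s_scaled$screen_pts <- s$screen_pts * k
    f1 <- unclass(extract_features(s))
    f2 <- unclass(extract_features(s_scaled))
    expected <- f1 * k^m$length_dim
    expect_equal(f2, expected, tolerance = 1e-10)
  }
})

test_that("features are invariant to a constant time shift (except first-touch latency)", {
  shift <- 3.7
  for (seed in c(21, 22)) {
    s <- random_session(seed, duration = 50)
    s$duration <- 60; validate_session(s)
    s_shift <- s
    s_shift$touch$t <- s$touch$t + shift
    s_shift$inertial$t <- s$inertial$t + shift
    validate_session(s_shift)
    f1 <- unclass(extract_features(s))
    f2 <- unclass(extract_features(s_shift))
    expect_equal(f2[["FirstTouchLatency"]], f1[["FirstTouchLatency"]] + shift)
    keep <- setdiff(names(f1), "FirstTouchLatency")
    expect_equal(f2[keep], f1[keep], tolerance = 1e-10)
  }
})

test_that("a window equal to the session duration reproduces single-pass extraction", {
  s <- random_session(31, duration = 40)
  f_single <- extract_features(s)
  f_win <- extract_features(s, window = s$duration)
  expect_equal(unclass(f_win), unclass(f_single))
})

test_that("windowed inertial values are the mean of per-window statistics", {
  n <- 41
  it <- inertial_df(seq(0, 4, by = 0.1), ax = c(rep(1, 20), rep(3, 21)))
  s <- game_session("c", "creativity", inertial = it, duration = 4)
  fv <- extract_features(s, window = 2)
  first <- it$ax[it$t < 2]; second <- it$ax[it$t >= 2]
  expect_equal(fv[["AccelMean_x"]], mean(c(mean(first), mean(second))))
})

test_that("cohort extraction returns one aligned row per session", {
  sessions <- lapply(1:3, function(i) random_session(40 + i, duration = 20))
  mat <- extract_cohort(sessions)
  expect_equal(nrow(mat), 3)
  expect_equal(ncol(mat), 262 + 5)
  expect_identical(colnames(mat)[1:5],
                   c("child_id", "game", "label", "age_months", "gender"))
  expect_identical(colnames(mat)[-(1:5)], feature_manifest()$name)
})
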