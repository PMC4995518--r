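test_that("two separated taps segment into two tap gestures", {
  touch <- rbind(tap_touch(1, 100, 100), tap_touch(2.1, 200, 200))
  s <- game_session("c", "sharing", touch = touch, duration = 5)
  g <- segment_gestures(s)
  expect_length(g, 2)
  expect_true(all(vapply(g, `[[`, logical(1), "is_tap")))
  expect_equal(vapply(g, `[[`, numeric(1), "t_start"), c(1, 2.1))
})

test_that("overlapping pointers merge into one multi-touch gesture", {
  touch <- touch_df(c(0, 0.1, 0.5, 0.6), c(0L, 1L, 0L, 1L),
                    c("began", "began", "ended", "ended"),
                    c(100, 120, 100, 120), c(100, 120, 100, 120))
  s <- game_session("c", "sharing", touch = touch, duration = 5)
  g <- segment_gestures(s)
  expect_length(g, 1)
  expect_equal(g[[1]]$n_pointers, 2)
  expect_equal(g[[1]]$t_end, 0.6)
  expect_false(g[[1]]$is_tap)
})

test_that("a drag of 30 moved samples is one 32-sample non-tap gesture", {
  touch <- drag_touch(0, 10, 10, 500, 400, dur = 1, n = 32)
  s <- game_session("c", "sharing", touch = touch, duration = 5)
  g <- segment_gestures(s)
  expect_length(g, 1)
  expect_equal(nrow(g[[1]]$samples), 32)
  expect_equal(sum(g[[1]]$samples$phase == "moved"), 30)
  expect_false(g[[1]]$is_tap)
})

test_that("the tap threshold is configurable", {
  short_drag <- drag_touch(0, 100, 100, 106, 100, dur = 0.1, n = 4)
  s <- game_session("c", "sharing", touch = short_drag, duration = 5)
  expect_true(segment_gestures(s, tap_path_epsilon = 10)[[1]]$is_tap)
  expect_false(segment_gestures(s, tap_path_epsilon = 2)[[1]]$is_tap)
})

test_that("gesture segmentation partitions every touch sample exactly once", {
  for (seed in 1:8) {
    s <- random_session(seed, duration = 40)
    g <- segment_gestures(s)
    counts <- vapply(g, function(x) nrow(x$samples), numeric(1))
    expect_equal(sum(counts), nrow(s$touch))
    # gestures are disjoint and sorted in time
    t_start <- vapply(g, `[[`, numeric(1), "t_start")
    t_end <- vapply(g, `[[`, numeric(1), "t_end")
    expect_true(all(diff(t_start) > 0))
    expect_true(all(t_start[-1] >= t_end[-length(t_end)]))
    # gesture count equals began events arriving while no pointer is down
    delta <- (s$touch$phase == "began") - (s$touch$phase == "ended")
    idle_before <- c(0, cumsum(delta)[-nrow(s$touch)]) == 0
    expect_length(g, sum(s$touch$phase == "began" & idle_before))
  }
})

test_that("segmentation of a written-then-read session equals the original", {
  s <- random_session(99, duration = 30)
  s2 <- read_session(write_session(s, compress = TRUE))
  g1 <- segment_gestures(s)
  g2 <- segment_gestures(s2)
  expect_length(g2, length(g1))
  expect_equal(lapply(g2, `[[`, "samples"), lapply(g1, `[[`, "samples"))
})

test_that("kinematics of a straight drag match hand arithmetic", {
  g <- make_gesture(drag_touch(0, 100, 100, 200, 100, dur = 0.5, n = 11))
  k <- gesture_kinematics(g)
  expect_equal(unname(k["path_length"]), 100)
  expect_equal(unname(k["mean_speed"]), 200)
  expect_equal(unname(k["straightness"]), 1)
  expect_equal(unname(k["x_extent"]), 100)
  expect_equal(unname(k["y_extent"]), 0)
  expect_equal(unname(k["area"]), 0)    # collinear
})

test_that("a tap has zero path, positive duration and area zero", {
  g <- make_gesture(tap_touch(0, 150, 150, dur = 0.08))
  k <- gesture_kinematics(g)
  expect_equal(unname(k["path_length"]), 0)
  expect_equal(unname(k["duration"]), 0.08)
  expect_equal(unname(k["mean_speed"]), 0)
  expect_equal(unname(k["area"]), 0)
  expect_equal(unname(k["straightness"]), 1)
})

test_that("an L-shaped path has straightness end-to-end over path length", {
  # 3 pts right then 4 pts up: path 7, end-to-end 5
  touch <- touch_df(c(0, 0.1, 0.2), 0L, c("began", "moved", "ended"),
                    c(0, 3, 3), c(0, 0, 4))
  k <- gesture_kinematics(make_gesture(touch))
  expect_equal(unname(k["path_length"]), 7)
  expect_equal(unname(k["straightness"]), 5 / 7)
})

test_that("multi-pointer path metrics follow the first pointer", {
  a <- drag_touch(0, 0, 0, 100, 0, dur = 1, n = 6, id = 0L)
  b <- drag_touch(0.1, 0, 50, 400, 50, dur = 0.8, n = 6, id = 1L)
  both <- rbind(a, b); both <- both[order(both$t), ]
  k <- gesture_kinematics(make_gesture(both))
  expect_equal(unname(k["path_length"]), 100)
  # but centroid/extents cover all samples
  expect_equal(unname(k["y_extent"]), 50)
})

test_that("convex-hull areas match the shoelace and fan-triangulation oracles", {
  sq <- make_gesture(touch_df(c(0, 0.1, 0.2, 0.3), 0L,
                              c("began", "moved", "moved", "ended"),
                              c(0, 1, 1, 0), c(0, 0, 1, 1)))
  expect_equal(gesture_area(sq), 1)
  tri <- make_gesture(touch_df(c(0, 0.1, 0.2), 0L,
                               c("began", "moved", "ended"),
                               c(0, 4, 0), c(0, 0, 3)))
  expect_equal(gesture_area(tri), 6)
  collinear <- make_gesture(drag_touch(0, 0, 0, 100, 100, dur = 1, n = 8))
  expect_equal(gesture_area(collinear), 0)

  # independent oracle: triangulate the hull as a fan of determinants
  fan_area <- function(x, y) {
    h <- grDevices::chull(x, y)
    if (length(h) < 3) return(0)
    hx <- x[h]; hy <- y[h]
    sum(vapply(2:(length(h) - 1), function(i) {
      det(rbind(c(hx[i] - hx[1], hy[i] - hy[1]),
                c(hx[i + 1] - hx[1], hy[i + 1] - hy[1]))) / 2
    }, numeric(1)))
  }
  set.seed(1)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    x <- runif(n, 0, 100); y <- runif(n, 0, 100)
    touch <- touch_df(seq(0, 1, length.out = n), 0L,
                      c("began", rep("moved", n - 2), "ended"), x, y)
    expect_equal(gesture_area(make_gesture(touch)), abs(fan_area(x, y)),
                 tolerance = 1e-12)
  }
})
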