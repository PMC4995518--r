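# Touch-stream synthesis: gameplay grammars over parametric gestures.
#
# Sharing: repeated cycles of one tap on the food item followed by four
# drags distributing the pieces to the four plates, then a 3 s reward
# pause. Creativity: free strokes and occasional taps at liberty. Both
# grammars place and pace gestures from the child's latent parameters.
#
# Internally gestures are plain lists of parallel vectors (t, id, phase,
# x, y); one data frame is assembled per session, which keeps simulation
# cheap enough to generate hundreds of 5-minute sessions in tests.

# Minimum-jerk position profile on [0, 1]: fraction of path covered. A
# per-child warp exponent skews the profile (children differ in where the
# speed peak falls) without changing path length or total duration.
min_jerk <- function(tau, warp = 1) {
  tau <- tau^warp
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

tap_g <- function(x, y, child) {
  dur <- child$tap_duration_floor + stats::rexp(1, rate = 1 / 0.05)
  list(t = c(0, dur), id = c(0L, 0L), phase = c("began", "ended"),
       x = c(x, x), y = c(y, y))
}

gesture_speed_draw <- function(child) {
  child$gesture_speed * stats::rlnorm(1, 0, child$speed_jitter_sd %||% 0.12)
}

# Sample a polyline at `rate` Hz with a bell-shaped (minimum-jerk) speed
# profile; total duration = path length / speed.
sample_path <- function(px, py, speed, rate, warp = 1) {
  seg <- sqrt(diff(px)^2 + diff(py)^2)
  L <- sum(seg)
  if (L <= 0 || speed <= 0) {
    # degenerate (fully clamped) path: emit a minimal press-release pair
    return(list(t = c(0, 0.05), id = c(0L, 0L),
                phase = c("began", "ended"),
                x = rep(px[1], 2), y = rep(py[1], 2)))
  }
  dur <- L / speed
  n <- max(3L, ceiling(dur * rate) + 1L)
  tau <- seq(0, 1, length.out = n)
  s_t <- min_jerk(tau, warp) * L
  cum <- c(0, cumsum(seg))
  keep <- c(TRUE, diff(cum) > 0)        # drop zero-length (clamped) segments
  x <- stats::approx(cum[keep], px[keep], xout = s_t, rule = 2)$y
  y <- stats::approx(cum[keep], py[keep], xout = s_t, rule = 2)$y
  list(t = tau * dur, id = rep(0L, n),
       phase = c("began", rep("moved", n - 2L), "ended"), x = x, y = y)
}

# Free stroke: a wavy circular arc starting from the child's gesture-height
# distribution. Arc length is a child trait independent of the area
# parameter; the subtended angle grows with the child's area parameter, so
# the hull fattens (area up) at constant path length.
free_stroke <- function(child, W, H, rate) {
  x0 <- clamp(stats::rnorm(1, child$gesture_height_mean * W,
                           child$gesture_height_sd * W), 8, W - 8)
  y0 <- clamp(stats::rnorm(1, H / 2, 0.22 * H), 8, H - 8)
  L <- (child$stroke_len %||% 260) * stats::rlnorm(1, 0, 0.24)
  phi <- clamp(1.05 * (child$gesture_area_scale^1.8) *
                 stats::rlnorm(1, 0, 0.08),
               0.15, 2 * pi)                   # subtended angle, rad
  r <- L / phi
  K <- 24L
  tau <- seq(0, 1, length.out = K + 1L)
  theta0 <- stats::runif(1, 0, 2 * pi)
  ang <- theta0 + tau * phi * sample(c(-1, 1), 1)
  wig <- 0.015 * (child$waviness %||% 1) * L *
    sin(2 * pi * 6 * tau + stats::runif(1, 0, 2 * pi))
  px <- r * cos(ang) + wig * cos(ang + pi / 2)
  py <- r * sin(ang) + wig * sin(ang + pi / 2)
  # centre the stroke on the drawn start point so the gesture centroid
  # follows the child's height distribution, not the arc geometry
  px <- clamp(px - mean(px) + x0, 4, W - 4)
  py <- clamp(py - mean(py) + y0, 4, H - 4)
  sample_path(px, py, gesture_speed_draw(child), rate,
              child$profile_warp %||% 1)
}

# Target drag: straight line plus a sinusoidal perpendicular bow.
target_drag <- function(from, to, child, W, H, rate) {
  d <- to - from
  dist <- sqrt(sum(d^2))
  K <- 16L
  tau <- seq(0, 1, length.out = K + 1L)
  perp <- c(-d[2], d[1]) / max(dist, 1)
  bow <- 0.08 * dist * stats::rnorm(1, 1, 0.4) * sin(pi * tau)
  px <- clamp(from[1] + tau * d[1] + bow * perp[1], 4, W - 4)
  py <- clamp(from[2] + tau * d[2] + bow * perp[2], 4, H - 4)
  sample_path(px, py, gesture_speed_draw(child), rate,
              child$profile_warp %||% 1)
}

# Occasionally turn a stroke into a two-finger gesture: a second pointer
# tracks the first at a small offset, beginning later and ending earlier.
add_second_pointer <- function(g, W, H) {
  n <- length(g$t)
  if (n < 6) return(g)
  idx <- 2:(n - 1)
  m <- length(idx)
  t <- c(g$t, g$t[idx])
  id <- c(g$id, rep(1L, m))
  phase <- c(g$phase, c("began", rep("moved", m - 2L), "ended"))
  x <- c(g$x, clamp(g$x[idx] + 22, 0, W))
  y <- c(g$y, clamp(g$y[idx] + 16, 0, H))
  o <- order(t, id)
  list(t = t[o], id = id[o], phase = phase[o], x = x[o], y = y[o])
}

gap_after <- function(meanlog, sdlog, child = NULL) {
  (if (is.null(child)) 1 else child$gap_scale %||% 1) *
    stats::rlnorm(1, meanlog, sdlog)
}

#' Simulate one child's gameplay session
#'
#' Generates the touch stream from the game's grammar and the child's
#' latent parameters, then derives the matching 10 Hz inertial stream with
#' [inertial_response()]. Deterministic given the child's seed.
#'
#' @param child a child row from [sample_cohort()] as a list (internally
#'   `child_profile()`), or a one-row `cohort` slice.
#' @param game `"sharing"` or `"creativity"`.
#' @param spec a [cohort_spec()].
#' @return a validated `game_session`.
#' @export
simulate_session <- function(child, game, spec = cohort_spec()) {
  if (inherits(child, "cohort")) child <- child_profile(child, 1L)
  game <- match.arg(game, c("sharing", "creativity"))
  seed <- derive_seed(child$seed, game)
  with_seed(seed, {
    touch <- simulate_touch_stream(child, game, spec)
    inertial <- inertial_response(touch, child, spec)
    game_session(
      child_id = child$child_id, game = game, phase = "test",
      duration = spec$duration, screen_pts = spec$screen_pts,
      label = child$label, age_months = child$age_months,
      gender = child$gender, touch = touch, inertial = inertial)
  })
}

simulate_touch_stream <- function(child, game, spec) {
  W <- spec$screen_pts[1]; H <- spec$screen_pts[2]
  rate <- spec$touch_rate
  dur <- spec$duration
  parts <- list()
  t <- stats::runif(1, 0.5, 2)

  emit <- function(g, t0) {
    if (t0 + max(g$t) > dur) return(FALSE)
    g$t <- g$t + t0
    parts[[length(parts) + 1L]] <<- g
    TRUE
  }

  if (game == "sharing") {
    food <- c(0.45 * W, 0.50 * H)
    plates <- list(c(0.20 * W, 0.20 * H), c(0.20 * W, 0.80 * H),
                   c(0.80 * W, 0.20 * H), c(0.80 * W, 0.80 * H))
    while (t < dur) {
      fx <- clamp(stats::rnorm(1, food[1], 0.04 * W), 8, W - 8)
      fy <- clamp(stats::rnorm(1, food[2], 0.06 * H), 8, H - 8)
      tap <- tap_g(fx, fy, child)
      if (!emit(tap, t)) break
      t <- t + max(tap$t) + gap_after(log(0.5), 0.4, child)
      done <- TRUE
      for (pl in plates) {
        to <- clamp(pl + stats::rnorm(2, 0, 0.03 * W), 8, c(W, H) - 8)
        g <- target_drag(c(fx, fy), to, child, W, H, rate)
        if (!emit(g, t)) { done <- FALSE; break }
        t <- t + max(g$t) + gap_after(log(0.5), 0.4, child)
      }
      if (!done) break
      t <- t + 3 + gap_after(log(0.5), 0.4, child)   # reward animation pause
    }
  } else {
    while (t < dur) {
      if (stats::runif(1) < 0.12) {
        x <- clamp(stats::rnorm(1, child$gesture_height_mean * W,
                                child$gesture_height_sd * W), 8, W - 8)
        y <- clamp(stats::rnorm(1, H / 2, 0.25 * H), 8, H - 8)
        g <- tap_g(x, y, child)
      } else {
        g <- free_stroke(child, W, H, rate)
        if (stats::runif(1) < 0.05) g <- add_second_pointer(g, W, H)
      }
      if (!emit(g, t)) break
      t <- t + max(g$t) + gap_after(log(0.7), 0.5, child)
    }
  }
  if (!length(parts)) return(empty_touch())
  data.frame(
    t = unlist(lapply(parts, `[[`, "t"), use.names = FALSE),
    id = unlist(lapply(parts, `[[`, "id"), use.names = FALSE),
    phase = unlist(lapply(parts, `[[`, "phase"), use.names = FALSE),
    x = unlist(lapply(parts, `[[`, "x"), use.names = FALSE),
    y = unlist(lapply(parts, `[[`, "y"), use.names = FALSE))
}
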