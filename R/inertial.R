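#' Synthesise the inertial response to a touch stream
#'
#' Builds the 10 Hz accelerometer / gyroscope / attitude stream a flat-lying
#' tablet would record while the given touch stream is played on it:
#'
#' * Gaussian baseline sensor noise on every axis;
#' * a damped-sinusoid acceleration impulse at every touch-down, with
#'   amplitude proportional to the child's impact force, split between the
#'   vertical (into-screen) and lateral axes by the child's lateral force
#'   share;
#' * a rotation-rate impulse proportional to impulse amplitude times the
#'   lever arm (touch point minus device centre), mixed across the three
#'   gyroscope axes through the group's axis-coupling matrix;
#' * a low-amplitude sustained pressure wobble during drag segments;
#' * attitude as a leaky integral of rotation rate.
#'
#' Uses the current RNG state; [simulate_session()] wraps it in the child's
#' session seed.
#'
#' @param touch a touch-event data frame (`t`, `id`, `phase`, `x`, `y`),
#'   time-sorted.
#' @param child a child parameter list (see [sample_cohort()]), including
#'   `impact_force`, `lateral_force_share` and the group `coupling` matrix.
#' @param spec a [cohort_spec()] (duration, rates, screen size).
#' @return inertial data frame (`t`, `ax..az`, `gx..gz`, `ox..oz`).
#' @export
inertial_response <- function(touch, child, spec = cohort_spec()) {
  dt <- 1 / spec$inertial_rate
  tg <- seq(0, spec$duration, by = dt)
  n <- length(tg)
  W <- spec$screen_pts[1]; H <- spec$screen_pts[2]
  M <- child$coupling
  stopifnot(is.matrix(M), all(dim(M) == c(3, 3)))

  nf <- child$noise_floor %||% 1   # per-device/child sensor noise floor
  acc <- matrix(stats::rnorm(3 * n, 0, 0.02 * nf), n, 3)   # g
  rot <- matrix(stats::rnorm(3 * n, 0, 0.03 * nf), n, 3)   # rad/s

  f_acc <- c(4.3, 3.6, 3.6)   # impulse carrier frequencies per axis, Hz
  f_rot <- c(3.1, 3.7, 2.6)
  tau_damp <- 0.20

  # random carrier phase per impulse: contact micro-timing differs touch
  # to touch, so impulses are sign-symmetric over a session
  impulse_shape <- function(tt, f, ph) exp(-tt / tau_damp) * sin(2 * pi * f * tt + ph)

  gain <- child$rotation_gain %||% 1   # contact/holding variability
  began <- which(touch$phase == "began")
  for (b in began) {
    t0 <- touch$t[b]
    A <- child$impact_force * stats::rlnorm(1, 0, 0.05)
    # supporting (non-primary) fingers land softly
    if (touch$id[b] > 0) A <- 0.3 * A
    # the lateral/vertical split varies touch to touch around the child's
    # habitual share (finger approach angle is not constant)
    lat <- clamp(child$lateral_force_share + stats::rnorm(1, 0, 0.15),
                 0.03, 0.92)
    i0 <- findInterval(t0, tg) + 1L
    i1 <- min(n, i0 + ceiling(0.6 / dt))
    sgn <- sample(c(-1, 1), 3, replace = TRUE)  # contact direction per axis
    ph_r <- stats::runif(3, 0, 2 * pi)
    if (i0 > n) next
    idx <- i0:i1
    tt <- tg[idx] - t0
    # force axes: signed exponential decay (the strike transient), with
    # per-sample contact jitter; signs are independent across axes so the
    # axes stay uncorrelated while |accel| tracks the strike force.
    # The longitudinal component reflects the fixed geometry of the
    # finger's approach, not the strike force.
    jit <- function() 1 + 0.12 * stats::rnorm(length(idx))
    decay <- exp(-tt / tau_damp)
    acc[idx, 1] <- acc[idx, 1] + 0.18 * sgn[1] * decay * jit()
    acc[idx, 2] <- acc[idx, 2] + lat * A * sgn[2] * decay * jit()
    acc[idx, 3] <- acc[idx, 3] + (1 - lat) * A * sgn[3] * decay * jit()
    # the very first sample after contact registers the full strike: a
    # vector of norm A along the axis-share direction
    dir <- c(0.18 * sgn[1], lat * sgn[2], (1 - lat) * sgn[3])
    acc[i0, ] <- acc[i0, ] + dir / sqrt(sum(dir^2)) * A *
      (1 + 0.05 * stats::rnorm(1))
    u <- (touch$x[b] - W / 2) / W
    v <- (touch$y[b] - H / 2) / H
    r0 <- 2.0 * gain * A * c(v, u, 0.5 * (abs(u) + abs(v)))
    raw <- cbind(r0[1] * impulse_shape(tt, f_rot[1], ph_r[1]),
                 r0[2] * impulse_shape(tt, f_rot[2], ph_r[2]),
                 r0[3] * impulse_shape(tt, f_rot[3], ph_r[3]))
    rot[idx, ] <- rot[idx, ] + raw %*% t(M)
  }

  # sustained pressure wobble over drag segments (>= 0.15 s press cycles)
  if (length(began)) {
    cyc <- press_cycles(touch)
    long <- cyc[cyc$t1 - cyc$t0 >= 0.15, , drop = FALSE]
    for (i in seq_len(nrow(long))) {
      idx <- which(tg >= long$t0[i] & tg <= long$t1[i])
      if (!length(idx)) next
      wA <- 0.12 * (child$wobble_gain %||% 1) * child$impact_force *
        child$lateral_force_share * stats::rlnorm(1, 0, 0.2)
      ph <- stats::runif(1, 0, 2 * pi)
      acc[idx, 2] <- acc[idx, 2] + wA * sin(2 * pi * 1.8 * tg[idx] + ph)
      rot[idx, 3] <- rot[idx, 3] + 0.5 * gain * wA * sin(2 * pi * 1.3 * tg[idx] + ph)
    }
  }

  # per-child sensor biases (same distribution in both groups)
  acc <- sweep(acc, 2, c(child$bias_ax %||% 0, child$bias_ay %||% 0,
                         child$bias_az %||% 0), "+")
  rot <- sweep(rot, 2, c(child$bias_gx %||% 0, child$bias_gy %||% 0,
                         child$bias_gz %||% 0), "+")

  att <- apply(rot, 2, function(g) {
    as.numeric(stats::filter(dt * g, 0.98, method = "recursive"))
  }) + matrix(stats::rnorm(3 * n, 0, 0.002), n, 3)

  data.frame(t = tg,
             ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
             gx = rot[, 1], gy = rot[, 2], gz = rot[, 3],
             ox = att[, 1], oy = att[, 2], oz = att[, 3])
}

# Press cycles (one per pointer touch-down .. release) of a touch stream.
press_cycles <- function(touch) {
  out <- list()
  for (pid in unique(touch$id)) {
    ph <- touch$phase[touch$id == pid]
    ts <- touch$t[touch$id == pid]
    b <- which(ph == "began"); e <- which(ph == "ended")
    k <- min(length(b), length(e))
    if (k) out[[length(out) + 1L]] <- data.frame(t0 = ts[b[seq_len(k)]],
                                                 t1 = ts[e[seq_len(k)]])
  }
  if (!length(out)) return(data.frame(t0 = numeric(0), t1 = numeric(0)))
  do.call(rbind, out)
}
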