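# Hand-built sessions and small generators used across test files.
# Deliberately independent of the package's synthetic-cohort simulator so
# that IO/segmentation/feature properties are not tested against the code
# that also produces the cohort fixtures.

touch_df <- function(t, id, phase, x, y) {
  data.frame(t = t, id = as.integer(id), phase = phase, x = x, y = y)
}

inertial_df <- function(t, ...) {
  vals <- list(...)
  base <- data.frame(t = t)
  for (col in c("ax", "ay", "az", "gx", "gy", "gz", "ox", "oy", "oz")) {
    base[[col]] <- if (!is.null(vals[[col]])) vals[[col]] else 0
  }
  base
}

# One tap (began + ended) at (x, y).
tap_touch <- function(t0, x, y, dur = 0.08, id = 0L) {
  touch_df(c(t0, t0 + dur), id, c("began", "ended"), x, y)
}

# A straight drag sampled at `n` points.
drag_touch <- function(t0, x0, y0, x1, y1, dur, n = 10, id = 0L) {
  tau <- seq(0, 1, length.out = n)
  touch_df(t0 + tau * dur, id,
           c("began", rep("moved", n - 2), "ended"),
           x0 + tau * (x1 - x0), y0 + tau * (y1 - y0))
}

# A random hand-rolled session: taps and straight drags, occasionally a
# two-finger gesture, on a 1024 x 768 screen.
random_session <- function(seed, duration = 60, game = "creativity") {
  set.seed(seed)
  parts <- list()
  t <- runif(1, 0.2, 1)
  while (t < duration - 2) {
    kind <- sample(c("tap", "drag", "multi"), 1, prob = c(0.4, 0.5, 0.1))
    x0 <- runif(1, 20, 1000); y0 <- runif(1, 20, 740)
    g <- if (kind == "tap") {
      tap_touch(t, x0, y0, dur = runif(1, 0.04, 0.2))
    } else if (kind == "drag") {
      drag_touch(t, x0, y0, runif(1, 20, 1000), runif(1, 20, 740),
                 dur = runif(1, 0.3, 1.2), n = sample(5:25, 1))
    } else {
      a <- drag_touch(t, x0, y0, min(x0 + 80, 1020), y0,
                      dur = 0.6, n = 8, id = 0L)
      b <- drag_touch(t + 0.1, min(x0 + 30, 1020), min(y0 + 30, 760),
                      min(x0 + 110, 1020), min(y0 + 30, 760),
                      dur = 0.35, n = 6, id = 1L)
      out <- rbind(a, b)
      out[order(out$t), ]
    }
    parts[[length(parts) + 1L]] <- g
    t <- max(g$t) + runif(1, 0.2, 1.5)
  }
  touch <- do.call(rbind, parts)
  rownames(touch) <- NULL
  nt <- floor(duration * 10) + 1
  it <- inertial_df(seq(0, duration, by = 0.1)[seq_len(nt)],
                    ax = rnorm(nt, 0, 0.05), ay = rnorm(nt, 0, 0.05),
                    az = rnorm(nt, 0, 0.05), gx = rnorm(nt, 0, 0.1),
                    gy = rnorm(nt, 0, 0.1), gz = rnorm(nt, 0, 0.1),
                    ox = rnorm(nt, 0, 0.02), oy = rnorm(nt, 0, 0.02),
                    oz = rnorm(nt, 0, 0.02))
  game_session("rand", game, touch = touch, inertial = it,
               duration = duration, label = sample(c("asd", "control"), 1))
}

make_gesture <- function(touch, tap_path_epsilon = 10) {
  s <- game_session("g", "creativity", touch = touch,
                    duration = max(touch$t) + 1)
  segment_gestures(s, tap_path_epsilon)[[1]]
}

# Synthetic prediction records.
pred_records <- function(p_asd, label, rep = 1L, game = "creativity") {
  data.frame(child_id = as.character(seq_along(p_asd)), game = game,
             rep = rep, fold = 1L, p_asd = p_asd, label = label,
             stringsAsFactors = FALSE)
}
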