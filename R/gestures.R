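#' Segment a touch stream into atomic gestures
#'
#' A gesture is one atomic interaction: it opens at a `began` event that
#' arrives while no pointer is down, and closes at the `ended` event that
#' returns the active-pointer count to zero. Taps, drags and multi-touch all
#' fall out of this single rule; every touch sample belongs to exactly one
#' gesture. A cancelled pointer (stream ends mid-gesture) closes its gesture
#' at the last seen sample, with a warning.
#'
#' @param session a validated `game_session`.
#' @param tap_path_epsilon path-length threshold (points) under which a
#'   single-pointer gesture counts as a tap (default 10).
#' @return list of `gesture` objects sorted by start time, each with fields
#'   `samples` (the touch rows), `t_start`, `t_end`, `n_pointers` (maximum
#'   simultaneously active pointers) and `is_tap`.
#' @export
segment_gestures <- function(session, tap_path_epsilon = 10) {
  stopifnot(inherits(session, "game_session"))
  tt <- session$touch
  n <- nrow(tt)
  if (!n) return(list())

  # Active-pointer counter sweep (vectorised; grammar already validated).
  delta <- (tt$phase == "began") - (tt$phase == "ended")
  active_after <- cumsum(delta)
  active_before <- c(0L, active_after[-n])
  gesture_of <- cumsum(tt$phase == "began" & active_before == 0L)
  if (active_after[n] > 0L) {
    warning("touch stream ends with pointer(s) still down; closing gesture at last sample",
            call. = FALSE)
  }

  unname(lapply(split(seq_len(n), gesture_of), function(idx) {
    new_gesture(tt[idx, , drop = FALSE], tap_path_epsilon)
  }))
}

new_gesture <- function(samples, tap_path_epsilon = 10) {
  rownames(samples) <- NULL
  n_pt <- max_concurrent_pointers(samples)
  single <- length(unique(samples$id)) == 1L
  structure(list(
    samples = samples,
    t_start = samples$t[1],
    t_end = samples$t[nrow(samples)],
    n_pointers = n_pt,
    is_tap = single && gesture_path_length(samples) < tap_path_epsilon
  ), class = "gesture")
}

max_concurrent_pointers <- function(samples) {
  delta <- ifelse(samples$phase == "began", 1L,
                  ifelse(samples$phase == "ended", -1L, 0L))
  max(cumsum(delta))
}

# Path length of the first pointer's trajectory (points).
gesture_path_length <- function(samples) {
  first <- samples$id == samples$id[1]
  x <- samples$x[first]; y <- samples$y[first]
  if (length(x) < 2) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' @export
print.gesture <- function(x, ...) {
  cat(sprintf("<gesture> [%.3f, %.3f] s | %d samples, %d pointer(s)%s\n",
              x$t_start, x$t_end, nrow(x$samples), x$n_pointers,
              if (x$is_tap) " | tap" else ""))
  invisible(x)
}
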