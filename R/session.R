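#' Construct a gameplay session object
#'
#' A `game_session` bundles everything recorded for one child playing one
#' game: a touch-event stream (pointer began/moved/ended events with screen
#' coordinates in points) and a nominally 10 Hz inertial stream (tri-axial
#' acceleration in g, rotation rate in rad/s, attitude Euler angles in rad).
#'
#' Coordinate convention: the device lies flat in landscape in front of the
#' seated child. `x` runs along the landscape long axis away from the child
#' (the "height" axis, 0 at the child-near edge); `y` runs laterally across
#' the short axis. Timestamps are float seconds from session start.
#'
#' @param child_id opaque child identifier.
#' @param game `"sharing"` or `"creativity"`.
#' @param touch data frame with columns `t`, `id` (pointer id), `phase`
#'   (`"began"`, `"moved"`, `"ended"`), `x`, `y`.
#' @param inertial data frame with columns `t`, `ax`, `ay`, `az` (accel, g),
#'   `gx`, `gy`, `gz` (rotation rate, rad/s), `ox`, `oy`, `oz` (attitude:
#'   pitch about x, roll about y, yaw about z, rad).
#' @param phase session phase, `"test"` (default) or `"training"`.
#' @param duration session length in seconds (default 300, the 5-minute test
#'   phase of the gameplay protocol).
#' @param screen_pts numeric length-2, screen width and height in points
#'   (landscape; default iPad-mini-like `c(1024, 768)`).
#' @param label optional group label, `"asd"` or `"control"`.
#' @param age_months,gender optional demographics (`gender` `"f"`/`"m"`).
#' @param validate run [validate_session()] on the result (default `TRUE`).
#' @return an object of class `game_session`.
#' @seealso [read_session()], [write_session()], [segment_gestures()]
#' @export
game_session <- function(child_id, game,
                         touch = empty_touch(), inertial = empty_inertial(),
                         phase = "test", duration = 300,
                         screen_pts = c(1024, 768),
                         label = NULL, age_months = NULL, gender = NULL,
                         validate = TRUE) {
  s <- structure(list(
    child_id = as.character(child_id),
    game = match.arg(game, c("sharing", "creativity")),
    phase = match.arg(phase, c("test", "training")),
    duration = as.numeric(duration),
    screen_pts = as.numeric(screen_pts),
    label = if (!is.null(label)) match.arg(label, c("asd", "control")),
    age_months = if (!is.null(age_months)) as.integer(age_months),
    gender = if (!is.null(gender)) match.arg(gender, c("f", "m")),
    touch = as.data.frame(touch),
    inertial = as.data.frame(inertial)
  ), class = "game_session")
  if (validate) validate_session(s)
  s
}

empty_touch <- function() {
  data.frame(t = numeric(0), id = integer(0), phase = character(0),
             x = numeric(0), y = numeric(0))
}

empty_inertial <- function() {
  data.frame(t = numeric(0),
             ax = numeric(0), ay = numeric(0), az = numeric(0),
             gx = numeric(0), gy = numeric(0), gz = numeric(0),
             ox = numeric(0), oy = numeric(0), oz = numeric(0))
}

#' Validate a gameplay session
#'
#' Checks the structural invariants of a session: streams independently
#' time-sorted with `t >= 0` and `t <= duration`, touch coordinates within
#' the screen, finite inertial components, and per-pointer phase grammar
#' `began -> moved* -> ended` (repeatable, since devices reuse pointer ids).
#' A pointer left down when its stream ends (a cancelled pointer) is allowed
#' with a warning; [segment_gestures()] closes it at its last sample.
#'
#' @param session a `game_session`.
#' @return the session, invisibly. Errors name the offending record index.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "game_session"))
  tt <- session$touch
  it <- session$inertial
  need <- c("t", "id", "phase", "x", "y")
  if (!all(need %in% names(tt))) {
    abort_parse("touch stream lacks column(s): %s",
                paste(setdiff(need, names(tt)), collapse = ", "))
  }
  if (nrow(tt)) {
    if (any(!is.finite(tt$t)) || any(tt$t < 0)) {
      abort_parse("touch record %d: negative or non-finite timestamp",
                  which(!is.finite(tt$t) | tt$t < 0)[1])
    }
    if (is.unsorted(tt$t)) {
      abort_parse("touch record %d: timestamps not sorted",
                  which(diff(tt$t) < 0)[1] + 1L)
    }
    if (any(tt$t > session$duration + 1e-9)) {
      abort_parse("touch record %d: timestamp exceeds session duration",
                  which(tt$t > session$duration + 1e-9)[1])
    }
    bad_phase <- !tt$phase %in% c("began", "moved", "ended")
    if (any(bad_phase)) {
      abort_parse("touch record %d: unknown phase '%s'",
                  which(bad_phase)[1], tt$phase[which(bad_phase)[1]])
    }
    oob <- tt$x < -1e-9 | tt$x > session$screen_pts[1] + 1e-9 |
      tt$y < -1e-9 | tt$y > session$screen_pts[2] + 1e-9
    if (any(oob)) {
      abort_parse("touch record %d: coordinates outside screen bounds",
                  which(oob)[1])
    }
    check_pointer_grammar(tt)
  }
  if (nrow(it)) {
    vals <- as.matrix(it[c("ax", "ay", "az", "gx", "gy", "gz",
                           "ox", "oy", "oz")])
    if (any(!is.finite(vals))) {
      abort_parse("inertial record %d: non-finite component",
                  which(rowSums(!is.finite(vals)) > 0)[1])
    }
    if (any(!is.finite(it$t)) || any(it$t < 0)) {
      abort_parse("inertial record %d: negative or non-finite timestamp",
                  which(!is.finite(it$t) | it$t < 0)[1])
    }
    if (is.unsorted(it$t)) {
      abort_parse("inertial record %d: timestamps not sorted",
                  which(diff(it$t) < 0)[1] + 1L)
    }
    if (any(it$t > session$duration + 1e-9)) {
      abort_parse("inertial record %d: timestamp exceeds session duration",
                  which(it$t > session$duration + 1e-9)[1])
    }
  }
  invisible(session)
}

# Per-pointer phase grammar: began -> moved* -> ended, repeatable.
# A trailing unfinished cycle (cancelled pointer) warns; bad transitions
# error with the offending record index.
check_pointer_grammar <- function(tt) {
  for (pid in unique(tt$id)) {
    idx <- which(tt$id == pid)
    ph <- tt$phase[idx]
    # down state after each event of this pointer
    down <- cumsum((ph == "began") - (ph == "ended"))
    down_before <- c(0L, down[-length(down)])
    bad_began <- ph == "began" & down_before != 0L
    bad_loose <- ph != "began" & down_before == 0L
    bad <- bad_began | bad_loose
    if (any(bad)) {
      j <- which(bad)[1]
      i <- idx[j]
      if (bad_loose[j]) {
        abort_parse("touch record %d: pointer %s '%s' before 'began'",
                    i, pid, tt$phase[i])
      }
      abort_parse("touch record %d: pointer %s 'began' while already down",
                  i, pid)
    }
    if (down[length(down)] > 0L) {
      warning(sprintf("pointer %s cancelled: stream ends mid-gesture", pid),
              call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.game_session <- function(x, ...) {
  cat(sprintf(
    "<game_session> child %s | %s game, %s phase, %.0f s\n  %d touch events, %d inertial samples%s\n",
    x$child_id, x$game, x$phase, x$duration, nrow(x$touch), nrow(x$inertial),
    if (!is.null(x$label)) paste0(" | label: ", x$label) else ""))
  invisible(x)
}
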