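#' Kinematic summary of one gesture
#'
#' Instantaneous speeds come from consecutive same-pointer position pairs
#' (`|delta position| / delta t`); accelerations from consecutive speed
#' differences. Path metrics (path length, speeds, accelerations,
#' straightness) use the first pointer of a multi-touch gesture; form
#' metrics (area, centroid, extents) use every sample.
#'
#' @param g a `gesture` from [segment_gestures()].
#' @return named numeric vector with elements `duration` (s), `path_length`
#'   (pts), `mean_speed` (path length / duration; 0 for an instantaneous
#'   gesture), `max_speed`, `mean_accel`, `max_accel` (means/maxima of
#'   absolute values), `area` (convex-hull pts^2), `height` (centroid x:
#'   distance up the screen away from the child), `lateral` (centroid y),
#'   `x_extent`, `y_extent`, `straightness` (end-to-end distance over path
#'   length; 1 for a point), `n_samples`.
#' @export
gesture_kinematics <- function(g) {
  stopifnot(inherits(g, "gesture"))
  s <- g$samples
  duration <- g$t_end - g$t_start
  first <- s$id == s$id[1]
  fx <- s$x[first]; fy <- s$y[first]; ft <- s$t[first]

  path <- if (length(fx) >= 2) sum(sqrt(diff(fx)^2 + diff(fy)^2)) else 0
  dt <- diff(ft)
  step <- if (length(fx) >= 2) sqrt(diff(fx)^2 + diff(fy)^2) else numeric(0)
  ok <- dt > 0
  speeds <- if (any(ok)) step[ok] / dt[ok] else numeric(0)
  accels <- if (length(speeds) >= 2) {
    tmid <- (ft[-1] + ft[-length(ft)])[ok] / 2
    dts <- diff(tmid)
    abs(diff(speeds))[dts > 0] / dts[dts > 0]
  } else numeric(0)

  ee <- if (length(fx) >= 2) sqrt((fx[length(fx)] - fx[1])^2 + (fy[length(fy)] - fy[1])^2) else 0

  c(duration = duration,
    path_length = path,
    mean_speed = if (duration > 0) path / duration else 0,
    max_speed = if (length(speeds)) max(speeds) else 0,
    mean_accel = if (length(accels)) mean(accels) else 0,
    max_accel = if (length(accels)) max(accels) else 0,
    area = hull_area(s$x, s$y),
    height = mean(s$x),
    lateral = mean(s$y),
    x_extent = diff(range(s$x)),
    y_extent = diff(range(s$y)),
    straightness = if (path > 0) min(ee / path, 1) else 1,
    n_samples = nrow(s))
}

#' Convex-hull area of a gesture's touch points
#'
#' The footprint a gesture occupies on screen, measured as the area of the
#' convex polygon fitted around all its touch points (shoelace formula on
#' the hull vertices). Fewer than 3 non-collinear points give 0.
#'
#' @param g a `gesture`.
#' @return area in pts^2.
#' @export
gesture_area <- function(g) {
  stopifnot(inherits(g, "gesture"))
  hull_area(g$samples$x, g$samples$y)
}

hull_area <- function(x, y) {
  keep <- !duplicated(x + 1i * y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) return(0)
  h <- grDevices::chull(x, y)
  if (length(h) < 3) return(0)
  hx <- x[h]; hy <- y[h]
  a <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  # collinear point sets must give exactly 0 at any coordinate scale
  span2 <- diff(range(x))^2 + diff(range(y))^2
  if (a <= 1e-10 * span2) 0 else a
}
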