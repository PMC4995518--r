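#' Summary statistics of one sensor-axis series
#'
#' The 15 per-axis statistics used throughout the inertial feature
#' catalogue. Standard deviation (and the moment-based skewness/kurtosis)
#' use the population (N) denominator; `energy` is the mean of squares
#' (so `rms = sqrt(energy)`); `zero_cross_rate` is the sign-change count per
#' second of recording.
#'
#' @param series numeric vector (one axis of one signal).
#' @param duration seconds of recording the series spans (> 0).
#' @return named numeric vector of length 15: `mean`, `std`, `rms`, `min`,
#'   `max`, `range`, `median`, `iqr`, `skewness`, `kurtosis` (excess),
#'   `zero_cross_count`, `zero_cross_rate`, `mean_abs`, `energy`,
#'   `mean_abs_diff`. All `NA` when `length(series) < 2`; skewness/kurtosis
#'   are `NA` for a constant series.
#' @export
axis_stats <- function(series, duration) {
  nm <- c("mean", "std", "rms", "min", "max", "range", "median", "iqr",
          "skewness", "kurtosis", "zero_cross_count", "zero_cross_rate",
          "mean_abs", "energy", "mean_abs_diff")
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0)
  if (length(series) < 2 || any(!is.finite(series))) {
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  }
  n <- length(series)
  m <- mean(series)
  dev <- series - m
  m2 <- mean(dev^2)
  s <- sqrt(m2)
  energy <- mean(series^2)
  zc <- zero_crossings(series)
  stats::setNames(c(
    m, s, sqrt(energy), min(series), max(series),
    max(series) - min(series), stats::median(series),
    stats::IQR(series),
    if (s > 0) mean(dev^3) / s^3 else NA_real_,
    if (s > 0) mean(dev^4) / m2^2 - 3 else NA_real_,
    zc, zc / duration, mean(abs(series)), energy,
    mean(abs(diff(series)))
  ), nm)
}

#' Count sign changes in a series
#'
#' Exact zeros are skipped: a crossing is a pair of consecutive *nonzero*
#' samples with opposite sign.
#'
#' @param series numeric vector.
#' @return integer count.
#' @export
zero_crossings <- function(series) {
  s <- sign(series)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

#' Per-sample Euclidean norm of a tri-axial signal
#'
#' @param xyz numeric matrix with 3 columns (one row per sample).
#' @return numeric vector of norms.
#' @export
magnitude_series <- function(xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) >= 1)
  sqrt(rowSums(xyz^2))
}

#' Pearson correlation between two axis series
#'
#' @param a,b numeric vectors of equal length (>= 2).
#' @return Pearson r in `[-1, 1]`; `NA` when either input is constant
#'   (the coefficient is undefined and the feature is masked).
#' @export
pairwise_corr <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}
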