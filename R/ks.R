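#' Two-sample Kolmogorov-Smirnov distance
#'
#' `D = sup_x |ECDF_a(x) - ECDF_b(x)|`, computed exactly (ties handled by
#' evaluating both ECDFs at every observed value). Missing values are
#' dropped first.
#'
#' @param a,b numeric samples (each non-empty after `NA` removal).
#' @return D in `[0, 1]`.
#' @export
ks_distance <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) {
    stop("ks_distance() needs non-empty samples after missing-value removal",
         call. = FALSE)
  }
  x <- sort(unique(c(a, b)))
  Fa <- vapply(x, function(v) mean(a <= v), numeric(1))
  Fb <- vapply(x, function(v) mean(b <= v), numeric(1))
  max(abs(Fa - Fb))
}

#' Direction of a group difference
#'
#' @param values numeric feature values.
#' @param labels `"asd"` / `"control"` per value.
#' @return `"higher_in_asd"`, `"lower_in_asd"` or `"null"` by the sign of
#'   `median(asd) - median(control)` (missing values dropped).
#' @export
effect_direction <- function(values, labels) {
  a <- values[labels == "asd"]; b <- values[labels == "control"]
  stopifnot(length(a) > 0, length(b) > 0)
  d <- stats::median(a, na.rm = TRUE) - stats::median(b, na.rm = TRUE)
  if (is.na(d) || d == 0) "null" else if (d > 0) "higher_in_asd" else "lower_in_asd"
}

#' Rank features by Kolmogorov-Smirnov distance between groups
#'
#' The feature-screening stage of the motor-signature analysis: every
#' feature's asd and control samples are compared by KS distance and the
#' features are ranked by descending D (ties broken by manifest order).
#' When the matrix has a `game` column, ranking is per game. KS p-values
#' (asymptotic, from [stats::ks.test()]) are reported for information only;
#' no multiple-testing correction is applied, as the screening is an
#' approximation of which features drive the classifier, not an inferential
#' procedure.
#'
#' @param features feature matrix from [extract_cohort()] (metadata columns
#'   plus feature columns), or any data frame of numeric feature columns.
#' @param labels `"asd"`/`"control"` per row; defaults to the matrix's
#'   `label` column.
#' @param top_k how many features to keep per game (default 10; a value
#'   beyond the feature count returns the full ranking).
#' @param manifest a [feature_manifest()] (scan/tie order).
#' @return data frame of class `ks_ranking`: `game`, `rank`, `feature`,
#'   `source`, `D`, `p_value`, `direction`, group medians and IQRs.
#' @export
rank_features <- function(features, labels = NULL, top_k = 10,
                          manifest = feature_manifest()) {
  features <- as.data.frame(features, check.names = FALSE)
  labels <- labels %||% features$label
  stopifnot(!is.null(labels), all(labels %in% c("asd", "control")),
            any(labels == "asd"), any(labels == "control"))
  games <- if ("game" %in% colnames(features)) unique(features$game) else NA
  feat_cols <- intersect(manifest$name, colnames(features))
  src <- stats::setNames(manifest$source, manifest$name)

  one_game <- function(g) {
    keep <- if (is.na(g)) rep(TRUE, nrow(features)) else features$game == g
    sub <- features[keep, , drop = FALSE]
    lab <- labels[keep]
    res <- lapply(feat_cols, function(f) {
      v <- as.numeric(sub[[f]])
      a <- v[lab == "asd" & !is.na(v)]
      b <- v[lab == "control" & !is.na(v)]
      if (!length(a) || !length(b)) {
        return(data.frame(feature = f, D = NA_real_, p_value = NA_real_,
                          direction = "null", median_asd = NA_real_,
                          median_control = NA_real_, iqr_asd = NA_real_,
                          iqr_control = NA_real_, stringsAsFactors = FALSE))
      }
      data.frame(
        feature = f, D = ks_distance(a, b),
        p_value = suppressWarnings(stats::ks.test(a, b)$p.value),
        direction = effect_direction(v[!is.na(v)], lab[!is.na(v)]),
        median_asd = stats::median(a), median_control = stats::median(b),
        iqr_asd = stats::IQR(a), iqr_control = stats::IQR(b),
        stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    # descending D; ties (and NA last) broken by manifest order, which is
    # the row order built above
    ord <- order(-ifelse(is.na(res$D), -1, res$D))
    res <- res[ord, , drop = FALSE]
    res <- utils::head(res, top_k)
    cbind(game = if (is.na(g)) "all" else g,
          rank = seq_len(nrow(res)), res,
          source = unname(src[res$feature]))
  }
  out <- do.call(rbind, lapply(games, one_game))
  rownames(out) <- NULL
  class(out) <- c("ks_ranking", "data.frame")
  out
}

#' @export
print.ks_ranking <- function(x, ...) {
  cat(sprintf("<ks_ranking> %d ranked feature(s)\n", nrow(x)))
  cols <- intersect(c("game", "rank", "feature", "source", "D", "direction"),
                    colnames(x))
  print.data.frame(as.data.frame(x)[cols], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Boxplot summary of a feature per group
#'
#' Median, quartiles, whiskers at 1.5 x IQR (Tukey convention) and outliers
#' for each group — the data behind a group-comparison boxplot.
#'
#' @param values numeric feature values.
#' @param labels `"asd"`/`"control"` per value.
#' @return named list of per-group lists (`median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `outliers`).
#' @export
boxplot_summary <- function(values, labels) {
  lapply(split(values[!is.na(values)], labels[!is.na(values)]), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    lo <- min(v[v >= q[1] - 1.5 * iqr])
    hi <- max(v[v <= q[3] + 1.5 * iqr])
    list(median = q[2], q1 = q[1], q3 = q[3],
         whisker_low = lo, whisker_high = hi,
         outliers = v[v < lo | v > hi])
  })
}
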