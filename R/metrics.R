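#' Area under the ROC curve of pooled prediction records
#'
#' Rank-based (Mann-Whitney) AUC of `p_asd` for the asd class against the
#' control class; tied scores count one half. Equals the probability that a
#' randomly chosen asd child scores above a randomly chosen control child.
#'
#' @param records prediction records from [run_cv()] (needs `p_asd`,
#'   `label`).
#' @return AUC in `[0, 1]`. Errors when only one class is present.
#' @export
auc <- function(records) {
  pos <- records$p_asd[records$label == "asd"]
  neg <- records$p_asd[records$label == "control"]
  if (!length(pos) || !length(neg)) {
    stop("auc() needs both classes present", call. = FALSE)
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Per-repetition AUC summary
#'
#' Computes AUC on each repetition's pooled out-of-fold predictions, then
#' the mean and standard deviation across repetitions (the convention used
#' for tabulated cross-validated AUCs; the pooled-over-everything AUC used
#' for ROC plots is [auc()] on all records).
#'
#' @param records prediction records from [run_cv()].
#' @return list with `mean`, `sd` (0 for a single repetition) and `per_rep`
#'   (named numeric, one AUC per repetition).
#' @export
auc_summary <- function(records) {
  per <- vapply(split(records, records$rep), auc, numeric(1))
  list(mean = mean(per),
       sd = if (length(per) > 1) stats::sd(per) else 0,
       per_rep = per)
}

#' Sensitivity and specificity at a threshold
#'
#' Predicts asd iff `p_asd >= threshold` (positive class = asd), counted
#' over all pooled records.
#'
#' @param records prediction records.
#' @param threshold classification threshold in `[0, 1]`.
#' @return named numeric: `sensitivity` (TP / (TP + FN)) and `specificity`
#'   (TN / (TN + FP)).
#' @export
sens_spec <- function(records, threshold) {
  stopifnot(any(records$label == "asd"), any(records$label == "control"))
  pred_pos <- records$p_asd >= threshold
  is_pos <- records$label == "asd"
  c(sensitivity = sum(pred_pos & is_pos) / sum(is_pos),
    specificity = sum(!pred_pos & !is_pos) / sum(!is_pos))
}

#' Average each child's predictions across the two games
#'
#' Pairs the two games' prediction records by child and repetition and
#' averages `p_asd`, giving per-child cross-game scores whose AUC is the
#' "average of both games" summary. Children missing from one game are
#' excluded with a warning.
#'
#' @param records_a,records_b prediction records of the two games.
#' @return averaged prediction records (`game = "average"`).
#' @export
average_games <- function(records_a, records_b) {
  common <- intersect(unique(records_a$child_id), unique(records_b$child_id))
  if (!length(common)) stop("no children common to both games", call. = FALSE)
  missing <- setdiff(union(unique(records_a$child_id),
                           unique(records_b$child_id)), common)
  if (length(missing)) {
    warning(sprintf("excluding %d child(ren) missing one game", length(missing)),
            call. = FALSE)
  }
  a <- records_a[records_a$child_id %in% common, ]
  b <- records_b[records_b$child_id %in% common, ]
  key <- function(d) paste(d$child_id, d$rep, sep = "\r")
  b <- b[match(key(a), key(b)), ]
  stopifnot(!anyNA(b$p_asd), all(a$label == b$label))
  out <- a
  out$p_asd <- (a$p_asd + b$p_asd) / 2
  out$game <- "average"
  out
}

#' ROC curve of pooled prediction records
#'
#' Standard threshold sweep over all distinct scores, from the strictest
#' threshold (nothing called positive) to the loosest. Starts at (0, 0),
#' ends at (1, 1), both coordinates non-decreasing; the trapezoidal
#' integral of the curve equals [auc()] exactly (ties are grouped).
#'
#' @param records prediction records.
#' @return object of class `roc_curve`: data frame with `threshold`, `fpr`,
#'   `tpr`, plus an `auc` attribute.
#' @export
roc_curve <- function(records) {
  stopifnot(any(records$label == "asd"), any(records$label == "control"))
  o <- order(records$p_asd, decreasing = TRUE)
  p <- records$p_asd[o]
  pos <- records$label[o] == "asd"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  last <- !duplicated(p, fromLast = TRUE)      # last index of each tie group
  tpr <- cumsum(pos)[last] / n_pos
  fpr <- cumsum(!pos)[last] / n_neg
  out <- data.frame(threshold = c(Inf, p[last]),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  structure(out, class = c("roc_curve", "data.frame"), auc = auc(records))
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x), attr(x, "auc")))
  invisible(x)
}

# Trapezoidal integral of a ROC curve (internal consistency check).
trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}
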