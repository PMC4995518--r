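#' Drop correlation-redundant features
#'
#' Scans features in manifest order and drops any feature whose absolute
#' Pearson correlation with an already-retained feature exceeds
#' `r_threshold` (pairs whose correlation is undefined — a constant column
#' or no complete observations — never trigger a drop). The first feature
#' of a correlated group, in manifest order, is the retained
#' representative; the procedure is deterministic.
#'
#' @param matrix numeric matrix or data frame, children x features, columns
#'   named by manifest feature names. `NA`s allowed (pairwise-complete
#'   correlations).
#' @param manifest a [feature_manifest()] giving the scan order.
#' @param r_threshold correlation threshold in (0, 1); default 0.9.
#' @return list with `retained` (character, in manifest order), `dropped`
#'   (character) and `representative` (named character: dropped feature ->
#'   retained feature that displaced it).
#' @export
reduce_redundant <- function(matrix, manifest = feature_manifest(),
                             r_threshold = 0.9) {
  stopifnot(r_threshold > 0, r_threshold < 1)
  m <- as.matrix(as.data.frame(matrix)[, intersect(manifest$name, colnames(matrix)),
                                       drop = FALSE])
  if (nrow(m) < 2) stop("reduce_redundant() needs >= 2 children", call. = FALSE)
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  ord <- colnames(m)
  retained <- character(0)
  representative <- character(0)
  for (f in ord) {
    r <- abs(cc[f, retained])
    hit <- which(!is.na(r) & r > r_threshold)
    if (length(hit)) {
      representative[f] <- retained[hit[1]]
    } else {
      retained <- c(retained, f)
    }
  }
  list(retained = retained, dropped = names(representative),
       representative = representative)
}
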