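#' Cross-validation configuration
#'
#' Configures the repeated stratified k-fold harness. Model specs follow
#' the study configurations: extremely randomised trees (`"et"`, 5000
#' trees), random forest (`"rf"`, 5000 trees), and the regularized greedy
#' forest configurations `"rgf"` / `"rgf2"` (500 trees; `"rgf2"` is the
#' same model with the age and gender features excluded). RGF itself is an
#' optional plug-in: when no RGF backend is registered the harness
#' substitutes a 500-tree random forest and records the substitution in the
#' run metadata (set `allow_fallback = FALSE` to error instead).
#'
#' @param k number of folds (default 10).
#' @param repetitions repeats of the whole procedure (default 10).
#' @param model one of `"et"`, `"rf"`, `"rgf"`, `"rgf2"`.
#' @param n_trees forest size; `NULL` takes the model spec's default
#'   (5000 for et/rf, 500 for rgf/rgf2).
#' @param stratified stratify folds by class (default `TRUE`).
#' @param base_seed integer; repetition r uses seed `base_seed + r`.
#' @param include_demographics append age (months) and gender (0/1) as
#'   features. Default `TRUE` except for `"rgf2"`, which excludes them by
#'   definition.
#' @param reduce how to apply correlation-redundancy reduction:
#'   `"fold"` (default; fitted on each training fold, applied to its test
#'   fold), `"global"` (whole-dataset, the in-sample variant) or `"none"`.
#' @param r_threshold redundancy threshold (default 0.9).
#' @param allow_fallback substitute a random forest when the requested
#'   model has no backend (default `TRUE`).
#' @return a `cv_config` list.
#' @export
cv_config <- function(k = 10, repetitions = 10, model = "rf", n_trees = NULL,
                      stratified = TRUE, base_seed = 1L,
                      include_demographics = NULL,
                      reduce = c("fold", "global", "none"),
                      r_threshold = 0.9, allow_fallback = TRUE) {
  model <- match.arg(model, c("et", "rf", "rgf", "rgf2"))
  stopifnot(is_count(k), k >= 2, is_count(repetitions))
  if (is.null(include_demographics)) include_demographics <- model != "rgf2"
  if (model == "rgf2" && include_demographics) {
    stop("model 'rgf2' excludes demographics by definition", call. = FALSE)
  }
  structure(list(
    k = as.integer(k), repetitions = as.integer(repetitions),
    model = model,
    n_trees = as.integer(n_trees %||% if (model %in% c("et", "rf")) 5000L else 500L),
    stratified = isTRUE(stratified), base_seed = as.integer(base_seed),
    include_demographics = isTRUE(include_demographics),
    reduce = match.arg(reduce), r_threshold = r_threshold,
    allow_fallback = isTRUE(allow_fallback)
  ), class = "cv_config")
}

#' Stratified fold assignment
#'
#' Deterministically (given `seed`) assigns each child to one of `k` folds.
#' Fold sizes differ by at most one; under stratification each class's
#' per-fold counts also differ by at most one (a class with fewer members
#' than folds triggers a fall back to plain k-fold with a warning).
#'
#' @param labels class label per child.
#' @param k number of folds.
#' @param seed integer seed.
#' @param stratified stratify by class (default `TRUE`).
#' @return integer vector of fold ids (1..k), one per child.
#' @export
make_folds <- function(labels, k, seed, stratified = TRUE) {
  n <- length(labels)
  stopifnot(n >= k, k >= 2)
  if (stratified && any(table(labels) < k)) {
    warning("a class has fewer members than folds; using plain k-fold",
            call. = FALSE)
    stratified <- FALSE
  }
  with_seed(seed, {
    fold <- integer(n)
    sizes <- integer(k)
    groups <- if (stratified) split(seq_len(n), labels) else list(seq_len(n))
    for (idx in groups) {
      idx <- sample(idx)
      base <- length(idx) %/% k
      extra <- length(idx) %% k
      # folds with the smallest running totals take this class's remainder
      order_f <- sample(k)                       # random tie-break
      order_f <- order_f[order(sizes[order_f])]
      per_fold <- rep(base, k)
      if (extra > 0) per_fold[order_f[seq_len(extra)]] <- base + 1L
      assign_to <- rep(seq_len(k), per_fold)
      fold[idx] <- assign_to
      sizes <- sizes + per_fold
    }
    fold
  })
}

# Forest backends. Both are probability forests from ranger; "et" uses the
# extremely-randomised split rule without bootstrapping.
fit_forest <- function(x, y, model, n_trees, seed) {
  y <- factor(y, levels = c("control", "asd"))
  args <- list(x = x, y = y, num.trees = n_trees, probability = TRUE,
               seed = seed, num.threads = 1L, respect.unordered.factors = TRUE)
  if (model == "et") {
    args <- c(args, list(splitrule = "extratrees", replace = FALSE,
                         sample.fraction = 1))
  }
  do.call(ranger::ranger, args)
}

predict_forest <- function(fit, x) {
  p <- stats::predict(fit, data = x)$predictions
  unname(p[, "asd"])
}

resolve_model <- function(config) {
  if (config$model %in% c("et", "rf")) {
    return(list(backend = config$model, requested = config$model,
                fallback = FALSE))
  }
  if (!config$allow_fallback) {
    stop(sprintf(
      "model '%s' requires the optional RGF backend, which is not available; use model = 'rf' or 'et' instead",
      config$model), call. = FALSE)
  }
  list(backend = "rf", requested = config$model, fallback = TRUE)
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repetition, assigns children to `k` folds, fits the configured
#' tree ensemble on `k - 1` folds and predicts the held-out fold, pooling
#' the out-of-fold class probabilities. Every child is scored exactly once
#' per repetition, so the pooled record count is `repetitions * n`.
#'
#' All preprocessing is fitted inside the training fold only: missing
#' feature values are imputed with training-fold medians, and (by default)
#' correlation-redundancy reduction is computed on the training fold and
#' applied to the test fold — no test-fold row influences either statistic.
#'
#' @param features numeric feature matrix / data frame (children x
#'   features), columns named by manifest features; may also carry
#'   `age_months` / `gender` columns used when demographics are included.
#' @param labels `"asd"` / `"control"` per child.
#' @param config a [cv_config()].
#' @param child_id optional identifiers (default row numbers).
#' @param game optional game tag stored in the records.
#' @param hook optional instrumentation callback, called per fold with a
#'   list (`repetition`, `fold`, `train_idx`, `test_idx`, `impute_values`,
#'   `retained`); used to audit train/test isolation.
#' @return data frame of prediction records (`child_id`, `game`, `rep`,
#'   `fold`, `p_asd`, `label`) with a `metadata` attribute (model
#'   requested/used, fallback flag, seeds).
#' @export
run_cv <- function(features, labels, config = cv_config(), child_id = NULL,
                   game = NA_character_, hook = NULL) {
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("asd", "control")))
  n <- length(labels)
  stopifnot(config$k <= n)
  features <- as.data.frame(features, check.names = FALSE)
  stopifnot(nrow(features) == n)
  child_id <- child_id %||% as.character(seq_len(n))

  manifest <- feature_manifest()
  feat_cols <- intersect(manifest$name, colnames(features))
  if (!length(feat_cols)) feat_cols <- setdiff(
    colnames(features), c("child_id", "game", "label", "age_months", "gender"))
  x_all <- as.matrix(as.data.frame(lapply(features[feat_cols], as.numeric),
                                   check.names = FALSE))
  colnames(x_all) <- feat_cols

  demo <- NULL
  if (config$include_demographics) {
    if (!all(c("age_months", "gender") %in% colnames(features))) {
      stop("include_demographics = TRUE but 'age_months'/'gender' columns are missing",
           call. = FALSE)
    }
    demo <- cbind(age_months = as.numeric(features$age_months),
                  gender = as.numeric(factor(features$gender,
                                             levels = c("f", "m"))) - 1)
  }

  resolved <- resolve_model(config)
  global_retained <- if (config$reduce == "global") {
    reduce_redundant(x_all, manifest, config$r_threshold)$retained
  }

  records <- vector("list", config$repetitions * config$k)
  ri <- 0L
  for (r in seq_len(config$repetitions)) {
    rep_seed <- config$base_seed + r
    folds <- make_folds(labels, config$k, rep_seed, config$stratified)
    for (f in seq_len(config$k)) {
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      x_tr <- x_all[train_idx, , drop = FALSE]
      x_te <- x_all[test_idx, , drop = FALSE]

      retained <- switch(config$reduce,
        fold = reduce_redundant(x_tr, manifest, config$r_threshold)$retained,
        global = global_retained,
        none = colnames(x_all))
      x_tr <- x_tr[, retained, drop = FALSE]
      x_te <- x_te[, retained, drop = FALSE]

      med <- apply(x_tr, 2, stats::median, na.rm = TRUE)
      med[is.na(med)] <- 0
      for (j in seq_along(med)) {
        x_tr[is.na(x_tr[, j]), j] <- med[j]
        x_te[is.na(x_te[, j]), j] <- med[j]
      }
      if (!is.null(demo)) {
        x_tr <- cbind(x_tr, demo[train_idx, , drop = FALSE])
        x_te <- cbind(x_te, demo[test_idx, , drop = FALSE])
      }
      if (!is.null(hook)) {
        hook(list(repetition = r, fold = f, train_idx = train_idx,
                  test_idx = test_idx, impute_values = med,
                  retained = retained))
      }
      fit <- fit_forest(x_tr, labels[train_idx], resolved$backend,
                        config$n_trees, seed = rep_seed * 1000L + f)
      p <- predict_forest(fit, x_te)
      ri <- ri + 1L
      records[[ri]] <- data.frame(
        child_id = child_id[test_idx], game = game, rep = r, fold = f,
        p_asd = p, label = labels[test_idx], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  attr(out, "metadata") <- list(
    model_requested = resolved$requested, model_used = resolved$backend,
    fallback = resolved$fallback, n_trees = config$n_trees,
    k = config$k, repetitions = config$repetitions,
    base_seed = config$base_seed, reduce = config$reduce,
    include_demographics = config$include_demographics)
  out
}
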