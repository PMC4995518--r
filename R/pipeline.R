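#' Pipeline configuration
#'
#' One configuration object drives the whole pipeline: simulate a cohort,
#' extract features, cross-validate, rank features, report. Defaults are
#' the study conditions (37/45 children, both games, 300 s sessions,
#' 10 x 10-fold CV).
#'
#' @param out_dir output directory; stage artefacts are written beneath it
#'   (`sessions/`, `features.csv`, `predictions_<game>.csv`,
#'   `ks_ranking.csv`, `report.json`).
#' @param seed master seed for the cohort.
#' @param spec a [cohort_spec()].
#' @param profile an [effect_profile()].
#' @param cv a [cv_config()].
#' @param top_k features per game in the KS ranking.
#' @param window optional inertial window length (seconds).
#' @return a `pipeline_config` list carrying a content hash (`hash`) that
#'   stage artefacts embed for provenance.
#' @export
pipeline_config <- function(out_dir, seed = 1L, spec = cohort_spec(),
                            profile = effect_profile(), cv = cv_config(),
                            top_k = 10, window = NULL) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), spec = spec,
              profile = profile, cv = cv, top_k = top_k, window = window)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration file
#'
#' Flat keys override the defaults of [cohort_spec()],
#' [effect_profile()] (`m` only), [cv_config()] and [pipeline_config()].
#'
#' @param path YAML (or JSON) file with any of: `seed`, `n_asd`,
#'   `n_control`, `duration`, `games`, `m`, `k`, `repetitions`, `model`,
#'   `n_trees`, `top_k`, `out_dir`.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path)
       else yaml::read_yaml(path)
  spec_args <- j[intersect(names(j), names(formals(cohort_spec)))]
  cv_args <- j[intersect(names(j), names(formals(cv_config)))]
  pipeline_config(
    out_dir = j$out_dir %||% ".",
    seed = j$seed %||% 1L,
    spec = do.call(cohort_spec, spec_args),
    profile = effect_profile(m = j$m %||% 1),
    cv = do.call(cv_config, cv_args),
    top_k = j$top_k %||% 10)
}

provenance <- function(config) {
  sprintf("# motorsig config_hash=%s seed=%d manifest=%s",
          config$hash, config$seed, attr(feature_manifest(), "version"))
}

write_csv_prov <- function(df, path, config) {
  con <- file(path, "w")
  writeLines(provenance(config), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

read_csv_prov <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE)
}

#' Pipeline stage: simulate the cohort's session logs
#'
#' Writes one `.json.gz` session log per child per game under
#' `<out_dir>/sessions/`, plus a cohort manifest CSV (`child_id`, `label`,
#' `age_months`, `gender`, `seed`).
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the vector of session file paths.
#' @export
pipeline_simulate <- function(config) {
  dir.create(file.path(config$out_dir, "sessions"), recursive = TRUE,
             showWarnings = FALSE)
  cohort <- sample_cohort(config$spec, config$profile, config$seed)
  write_csv_prov(as.data.frame(cohort)[c("child_id", "label", "age_months",
                                         "gender", "seed")],
                 file.path(config$out_dir, "cohort.csv"), config)
  paths <- character(0)
  for (i in seq_len(nrow(cohort))) {
    ch <- child_profile(cohort, i)
    for (game in config$spec$games) {
      s <- simulate_session(ch, game, config$spec)
      p <- file.path(config$out_dir, "sessions",
                     sprintf("%s_%s.json.gz", ch$child_id, game))
      write_session_file(s, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Pipeline stage: extract the feature matrix
#'
#' Reads every session log under `<out_dir>/sessions/` and writes
#' `features.csv` (one row per child per game: metadata columns then the
#' manifest features). Corrupt session files are skipped with a warning.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the feature matrix.
#' @export
pipeline_extract <- function(config) {
  dir <- file.path(config$out_dir, "sessions")
  if (!dir.exists(dir)) {
    stop("missing upstream stage: no 'sessions/' directory — run pipeline_simulate() first",
         call. = FALSE)
  }
  files <- sort(list.files(dir, pattern = "\\.json(\\.gz)?$",
                           full.names = TRUE))
  sessions <- list()
  n_bad <- 0L
  for (f in files) {
    s <- tryCatch(read_session(f), error = function(e) {
      warning(sprintf("skipping corrupt session file %s: %s",
                      basename(f), conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(s)) n_bad <- n_bad + 1L else sessions[[length(sessions) + 1L]] <- s
  }
  features <- extract_cohort(sessions, window = config$window)
  attr(features, "n_skipped") <- n_bad
  write_csv_prov(features, file.path(config$out_dir, "features.csv"), config)
  invisible(features)
}

#' Pipeline stage: cross-validated classification
#'
#' Runs the repeated stratified k-fold harness per game, writes
#' `predictions_<game>.csv` plus `predictions_average.csv` (per-child mean
#' of both games, when both were run) and `metrics.json`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) named list of prediction-record data frames.
#' @export
pipeline_crossval <- function(config) {
  fp <- file.path(config$out_dir, "features.csv")
  if (!file.exists(fp)) {
    stop("missing upstream stage: no 'features.csv' — run pipeline_extract() first",
         call. = FALSE)
  }
  features <- read_csv_prov(fp)
  out <- list()
  for (game in intersect(config$spec$games, unique(features$game))) {
    sub <- features[features$game == game, , drop = FALSE]
    out[[game]] <- run_cv(sub, sub$label, config$cv,
                          child_id = sub$child_id, game = game)
  }
  if (all(c("sharing", "creativity") %in% names(out))) {
    out$average <- average_games(out$sharing, out$creativity)
  }
  metrics <- lapply(out, function(rec) {
    s <- auc_summary(rec)
    list(auc_mean = s$mean, auc_sd = s$sd, pooled_auc = auc(rec),
         sens_spec_0.50 = as.list(sens_spec(rec, 0.50)),
         sens_spec_0.55 = as.list(sens_spec(rec, 0.55)),
         n_records = nrow(rec), metadata = attr(rec, "metadata"))
  })
  for (g in names(out)) {
    write_csv_prov(out[[g]], file.path(config$out_dir,
                                       sprintf("predictions_%s.csv", g)),
                   config)
  }
  jsonlite::write_json(
    c(list(config_hash = config$hash, seed = config$seed), metrics),
    file.path(config$out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Pipeline stage: Kolmogorov-Smirnov feature ranking
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the `ks_ranking` data frame (written to
#'   `ks_ranking.csv`).
#' @export
pipeline_rank <- function(config) {
  fp <- file.path(config$out_dir, "features.csv")
  if (!file.exists(fp)) {
    stop("missing upstream stage: no 'features.csv' — run pipeline_extract() first",
         call. = FALSE)
  }
  features <- read_csv_prov(fp)
  ranking <- rank_features(features, top_k = config$top_k)
  write_csv_prov(ranking, file.path(config$out_dir, "ks_ranking.csv"), config)
  invisible(ranking)
}

#' Pipeline stage: summary report
#'
#' Collates the cohort, CV metrics and KS ranking into one `report.json`
#' (the synthetic-cohort analogues of a model-comparison table, a
#' sensitivity/specificity table and a top-features table). When the pooled
#' AUC of every game lies in the random band `[0.35, 0.65]`, the report
#' flags non-discrimination.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the report list.
#' @export
pipeline_report <- function(config) {
  mp <- file.path(config$out_dir, "metrics.json")
  kp <- file.path(config$out_dir, "ks_ranking.csv")
  for (p in c(mp, kp)) {
    if (!file.exists(p)) {
      stop(sprintf("missing upstream stage: no '%s' — run the %s stage first",
                   basename(p),
                   if (p == mp) "crossval" else "rank"), call. = FALSE)
    }
  }
  metrics <- jsonlite::fromJSON(mp, simplifyVector = TRUE)
  ranking <- read_csv_prov(kp)
  cohort <- read_csv_prov(file.path(config$out_dir, "cohort.csv"))
  games <- setdiff(names(metrics), c("config_hash", "seed"))
  pooled <- vapply(games, function(g) metrics[[g]]$pooled_auc, numeric(1))
  report <- list(
    config_hash = config$hash, seed = config$seed,
    manifest_version = attr(feature_manifest(), "version"),
    cohort = list(n = nrow(cohort),
                  n_asd = sum(cohort$label == "asd"),
                  n_control = sum(cohort$label == "control")),
    auc_table = lapply(metrics[games], function(m)
      m[c("auc_mean", "auc_sd", "pooled_auc", "n_records")]),
    sens_spec_table = lapply(metrics[games], function(m)
      m[c("sens_spec_0.50", "sens_spec_0.55")]),
    top_features = ranking[c("game", "rank", "feature", "source", "D",
                             "direction")],
    non_discrimination = all(pooled >= 0.35 & pooled <= 0.65))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}
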