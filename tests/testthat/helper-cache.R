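# Session-level cache so expensive simulated-cohort computations are shared
# between the module tests and the acceptance suite.

.tcache <- new.env(parent = emptyenv())

cache_get <- function(name, expr) {
  if (!exists(name, envir = .tcache, inherits = FALSE)) {
    assign(name, force(expr), envir = .tcache)
  }
  get(name, envir = .tcache, inherits = FALSE)
}

# Simulate a cohort and extract its feature matrix for one game.
sim_cohort_features <- function(n_asd, n_control, m, seed,
                                game = "creativity", duration = 300) {
  spec <- cohort_spec(n_asd = n_asd, n_control = n_control,
                      duration = duration, games = game)
  cohort <- sample_cohort(spec, effect_profile(m = m), seed = seed)
  sessions <- lapply(seq_len(nrow(cohort)), function(i)
    simulate_session(motorsig:::child_profile(cohort, i), game, spec))
  extract_cohort(sessions)
}

# The seven generator-manipulated features and their encoded directions.
MANIPULATED_FEATURES <- c(
  AccelerationMagnitudeMax = "higher_in_asd",
  AccelRMS_y = "higher_in_asd",
  Velocity = "higher_in_asd",
  AvgGestArea = "higher_in_asd",
  AvgGesturesHeight = "higher_in_asd",
  GesturesHeightStdDev = "higher_in_asd",
  GestureDurationMin = "lower_in_asd")

# Full KS rankings of five independently seeded 200 + 200 cohorts at the
# default effect profile (the generator-calibration study condition).
calibration_rankings <- function() {
  cache_get("calibration_rankings", lapply(1:5, function(seed) {
    feats <- sim_cohort_features(200, 200, m = 1, seed = 1000L + seed)
    rank_features(feats, top_k = Inf)
  }))
}

# Median pooled AUC over five seeds at each effect multiplier, on small
# independently seeded cohorts (monotonicity study).
monotone_auc_medians <- function() {
  cache_get("monotone_auc_medians", {
    ms <- c(0, 0.5, 1, 2)
    sapply(ms, function(m) {
      aucs <- sapply(1:5, function(seed) {
        feats <- sim_cohort_features(15, 15, m = m,
                                     seed = 2000L + seed * 10 + round(m * 2),
                                     duration = 120)
        rec <- run_cv(feats, feats$label,
                      cv_config(k = 5, repetitions = 2, model = "rf",
                                n_trees = 200, base_seed = seed),
                      child_id = feats$child_id)
        auc(rec)
      })
      stats::median(aucs)
    })
  })
}
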