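# A small labelled Gaussian feature matrix for harness tests: `sep` is the
# distance (in sd units) between the group means on each informative column.
gauss_features <- function(n_asd, n_control, p = 10, sep = 0, seed = 1) {
  set.seed(seed)
  n <- n_asd + n_control
  labels <- c(rep("asd", n_asd), rep("control", n_control))
  x <- matrix(rnorm(n * p), n, p)
  x[labels == "asd", ] <- x[labels == "asd", ] + sep
  colnames(x) <- feature_manifest()$name[seq_len(p)]
  df <- as.data.frame(x)
  df$age_months <- sample(36:83, n, replace = TRUE)
  df$gender <- sample(c("f", "m"), n, replace = TRUE)
  list(features = df, labels = labels)
}

test_that("stratified folds are balanced overall and per class", {
  labels <- c(rep("asd", 37), rep("control", 45))
  f <- make_folds(labels, k = 10, seed = 3)
  expect_equal(sort(unique(f)), 1:10)
  sizes <- tabulate(f, 10)
  expect_true(all(sizes %in% 8:9))
  per_class <- table(labels, f)
  expect_true(all(per_class["asd", ] %in% 3:4))
  expect_true(all(per_class["control", ] %in% 4:5))
  # same seed reproduces the assignment exactly
  expect_identical(f, make_folds(labels, k = 10, seed = 3))
  expect_false(identical(f, make_folds(labels, k = 10, seed = 4)))
})

test_that("tiny stratified folds keep one member of each class", {
  f <- make_folds(c("a", "a", "b", "b"), k = 2, seed = 1)
  expect_equal(unname(tabulate(f, 2)), c(2, 2))
  expect_length(unique(f[1:2]), 2)   # the two a's land in different folds
  expect_warning(make_folds(c("a", rep("b", 9)), k = 5, seed = 1),
                 "plain k-fold")
})

test_that("the pooled record count is repetitions times cohort size", {
  d <- gauss_features(10, 10, sep = 0, seed = 2)
  cfg <- cv_config(k = 10, repetitions = 10, model = "rf", n_trees = 30,
                   base_seed = 9)
  rec <- run_cv(d$features, d$labels, cfg)
  expect_equal(nrow(rec), 200)
  # each child appears exactly once per repetition
  counts <- table(rec$child_id, rec$rep)
  expect_true(all(counts == 1))
})

test_that("widely separated clusters are classified perfectly", {
  d <- gauss_features(10, 10, sep = 10, seed = 5)
  cfg <- cv_config(k = 10, repetitions = 2, model = "rf", n_trees = 100,
                   base_seed = 1)
  rec <- run_cv(d$features, d$labels, cfg)
  expect_equal(auc(rec), 1)
})

test_that("permuted labels classify at chance", {
  d <- gauss_features(20, 20, sep = 0, seed = 6)
  aucs <- sapply(1:5, function(s) {
    perm <- motorsig:::with_seed(s, sample(d$labels))
    rec <- run_cv(d$features, perm,
                  cv_config(k = 5, repetitions = 4, model = "rf",
                            n_trees = 100, base_seed = s))
    auc(rec)
  })
  expect_gte(mean(aucs), 0.35)
  expect_lte(mean(aucs), 0.65)
})

test_that("fixed seeds make ET and RF runs fully reproducible", {
  d <- gauss_features(8, 8, sep = 1, seed = 7)
  for (model in c("et", "rf")) {
    cfg <- cv_config(k = 4, repetitions = 2, model = model, n_trees = 50,
                     base_seed = 11)
    r1 <- run_cv(d$features, d$labels, cfg)
    r2 <- run_cv(d$features, d$labels, cfg)
    expect_identical(r1$p_asd, r2$p_asd)
  }
})

test_that("in-fold preprocessing never touches test-fold rows", {
  d <- gauss_features(9, 9, sep = 0.5, seed = 8)
  # plant missingness and an extreme child so fold medians differ
  d$features[1, 1] <- NA
  d$features[2, 2] <- NA
  d$features[3, 1] <- 50
  audits <- list()
  hook <- function(info) audits[[length(audits) + 1L]] <<- info
  cfg <- cv_config(k = 3, repetitions = 2, model = "rf", n_trees = 20,
                   base_seed = 4, reduce = "none")
  x <- d$features[, feature_manifest()$name[1:10]]
  run_cv(d$features, d$labels, cfg, hook = hook)
  expect_length(audits, 6)
  for (a in audits) {
    expect_length(intersect(a$train_idx, a$test_idx), 0)
    expect_setequal(c(a$train_idx, a$test_idx), seq_len(18))
    for (f in names(a$impute_values)) {
      expect_equal(a$impute_values[[f]],
                   median(x[a$train_idx, f], na.rm = TRUE))
    }
  }
})

test_that("redundancy reduction inside CV is fitted on the training fold", {
  d <- gauss_features(10, 10, p = 6, sep = 0, seed = 12)
  d$features[[2]] <- d$features[[1]]          # duplicate column
  audits <- list()
  cfg <- cv_config(k = 4, repetitions = 1, model = "rf", n_trees = 20,
                   base_seed = 2, reduce = "fold")
  run_cv(d$features, d$labels, cfg,
         hook = function(info) audits[[length(audits) + 1L]] <<- info)
  nm <- feature_manifest()$name
  for (a in audits) {
    expect_true(nm[1] %in% a$retained)
    expect_false(nm[2] %in% a$retained)
  }
})

test_that("unavailable RGF backend substitutes with metadata or errors on request", {
  d <- gauss_features(6, 6, sep = 2, seed = 13)
  cfg <- cv_config(k = 3, repetitions = 1, model = "rgf", n_trees = 20,
                   base_seed = 1)
  rec <- run_cv(d$features, d$labels, cfg)
  md <- attr(rec, "metadata")
  expect_true(md$fallback)
  expect_equal(md$model_requested, "rgf")
  expect_equal(md$model_used, "rf")
  cfg2 <- cv_config(k = 3, repetitions = 1, model = "rgf2", n_trees = 20,
                    base_seed = 1, allow_fallback = FALSE)
  expect_error(run_cv(d$features, d$labels, cfg2), "use model = 'rf'")
})

test_that("demographics are required only when included", {
  d <- gauss_features(6, 6, sep = 1, seed = 14)
  no_demo <- d$features[setdiff(names(d$features), c("age_months", "gender"))]
  cfg <- cv_config(k = 3, repetitions = 1, model = "rf", n_trees = 20)
  expect_error(run_cv(no_demo, d$labels, cfg), "age_months")
  cfg2 <- cv_config(k = 3, repetitions = 1, model = "rf", n_trees = 20,
                    include_demographics = FALSE)
  expect_silent(run_cv(no_demo, d$labels, cfg2))
})
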