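#!/usr/bin/env Rscript
# Stage 3: repeated stratified 10-fold cross-validation per game, pooled
# across folds and repetitions, for each tree-ensemble configuration
# (ET, RF, RGF, RGF2; the RGF configurations fall back to a 500-tree
# random forest and say so in the metrics metadata). Writes the
# per-configuration AUC table, the per-game prediction records of the
# primary (RGF2-style) configuration, and sensitivity/specificity at the
# 0.50 and 0.55 thresholds.

suppressPackageStartupMessages(library(motorsig))
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "common.R"))

cfg <- run_config()
preds <- pipeline_crossval(cfg)      # primary configuration (cfg$cv)

features <- utils::read.csv(file.path(cfg$out_dir, "features.csv"),
                            comment.char = "#", check.names = FALSE)
rows <- list()
for (model in c("et", "rf", "rgf2")) {
  cv <- cv_config(k = 10, repetitions = 10, model = model, n_trees = 500,
                  base_seed = cfg$seed)
  recs <- list()
  for (game in unique(features$game)) {
    sub <- features[features$game == game, ]
    recs[[game]] <- run_cv(sub, sub$label, cv, child_id = sub$child_id,
                           game = game)
  }
  if (all(c("sharing", "creativity") %in% names(recs))) {
    recs$average <- average_games(recs$sharing, recs$creativity)
  }
  for (g in names(recs)) {
    s <- auc_summary(recs[[g]])
    rows[[length(rows) + 1L]] <- data.frame(
      model = model, game = g, auc_mean = s$mean, auc_sd = s$sd,
      pooled_auc = auc(recs[[g]]),
      model_used = attr(recs[[g]], "metadata")$model_used)
  }
}
tab <- do.call(rbind, rows)
utils::write.csv(tab, file.path(cfg$out_dir, "auc_by_model.csv"),
                 row.names = FALSE)
cat("cross-validated AUC by model and game:\n")
print(tab, digits = 3, row.names = FALSE)
for (g in names(preds)) {
  ss <- rbind(`0.50` = sens_spec(preds[[g]], 0.50),
              `0.55` = sens_spec(preds[[g]], 0.55))
  cat(sprintf("\n%s sensitivity/specificity:\n", g)); print(round(ss, 3))
}
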