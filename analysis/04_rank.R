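#!/usr/bin/env Rscript
# Stage 4: rank features by two-sample Kolmogorov-Smirnov distance between
# the ASD-like and control-like groups, per game, with effect directions
# and boxplot summaries for the top features.

suppressPackageStartupMessages(library(motorsig))
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "common.R"))

cfg <- run_config()
ranking <- pipeline_rank(cfg)
cat("top features by KS distance:\n")
print(ranking)

features <- utils::read.csv(file.path(cfg$out_dir, "features.csv"),
                            comment.char = "#", check.names = FALSE)
box <- lapply(split(ranking, ranking$game), function(r) {
  game <- r$game[1]
  sub <- features[features$game == game, ]
  stats::setNames(lapply(r$feature, function(f)
    boxplot_summary(sub[[f]], sub$label)), r$feature)
})
jsonlite::write_json(box, file.path(cfg$out_dir, "boxplots.json"),
                     auto_unbox = TRUE, digits = NA)
cat("wrote", file.path(cfg$out_dir, "ks_ranking.csv"), "and boxplots.json\n")
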