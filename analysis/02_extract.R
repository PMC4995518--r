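#!/usr/bin/env Rscript
# Stage 2: read every session log and extract the 262-feature catalogue,
# one row per child per game, into features.csv.

suppressPackageStartupMessages(library(motorsig))
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "common.R"))

cfg <- run_config()
features <- pipeline_extract(cfg)
masked <- sum(is.na(features[feature_columns(features)]))
cat(sprintf("extracted %d x %d feature matrix (%d masked cells) -> %s\n",
            nrow(features), ncol(features), masked,
            file.path(cfg$out_dir, "features.csv")))
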