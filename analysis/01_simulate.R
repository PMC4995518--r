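#!/usr/bin/env Rscript
# Stage 1: simulate the default two-group cohort (37 ASD-like + 45
# control-like children, one 300 s test session per child per game) and
# write the session logs plus the cohort manifest under results/run/.

suppressPackageStartupMessages(library(motorsig))
source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))), "common.R"))

cfg <- run_config()
paths <- pipeline_simulate(cfg)
cat(sprintf("wrote %d session logs and %s\n", length(paths),
            file.path(cfg$out_dir, "cohort.csv")))
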