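# Shared configuration for the analysis drivers. Every stage reads the same
# pipeline_config so artefacts carry one config hash; pass --seed <int> to
# any stage to rerun the whole analysis under a different master seed.
#
# The cross-validation configuration is the study design (10 repetitions of
# stratified 10-fold CV, RGF2-style: demographics excluded) with 500-tree
# forests.

run_config <- function() {
  args <- commandArgs(trailingOnly = TRUE)
  seed <- 1L
  if (length(args) >= 2 && args[1] == "--seed") seed <- as.integer(args[2])
  pipeline_config(
    out_dir = file.path("results", sprintf("run_seed%d", seed)),
    seed = seed,
    spec = cohort_spec(),
    profile = effect_profile(m = 1),
    cv = cv_config(k = 10, repetitions = 10, model = "rgf2", n_trees = 500,
                   base_seed = seed),
    top_k = 10)
}
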