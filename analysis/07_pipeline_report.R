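#!/usr/bin/env Rscript
# End-to-end orchestration check: the same study-condition analysis driven
# by run_pipeline() from a single config, producing report.json/report.md.
source("analysis/00_config.R")

cfg <- list(
  seed = MASTER_SEED,
  simulation = list(rng_seed = stage_seed(MASTER_SEED, "study-population")),
  analysis = list(n_perm_distogram = 999, n_perm_mantel = 499,
                  n_perm_fst = 500),
  density = NULL)
rep <- run_pipeline(cfg, out_dir = "results/pipeline")
print(rep)
cat("Consolidated report at results/pipeline/report.md\n")
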