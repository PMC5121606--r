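# Shared settings for the analysis workflow. Each numbered script is a thin
# driver over the finesgs package; all tables land under results/.
suppressPackageStartupMessages(library(finesgs))

`%||%` <- function(a, b) if (is.null(a)) b else a

MASTER_SEED <- 1L
DATA_DIR <- "results/data"

# Study-condition population: 20 x 20 m plot, two consecutive cohorts of
# 100 plants, 10 SSR loci + 1 plastid haplotype, limited seed dispersal
# (mean 0.3 m), short-distance pollen flow, 15% inter-annual migrants.
study_sim_config <- function(seed = MASTER_SEED) {
  sim_config(rng_seed = stage_seed(seed, "study-population"))
}

# Permutation effort for the workflow runs (distogram envelopes use the
# heaviest setting; Mantel and F_ST tests follow the study's counts).
study_analysis_config <- function(seed = MASTER_SEED) {
  analysis_config(n_perm_distogram = 999L, n_perm_mantel = 999L,
                  n_perm_fst = 500L, rng_seed = stage_seed(seed, "analysis"))
}

load_study_data <- function() {
  if (!file.exists(file.path(DATA_DIR, "genotypes.csv")))
    stop("run analysis/01_simulate.R first")
  list(genotypes = read_genotypes(file.path(DATA_DIR, "genotypes.csv"), "csv"),
       frame = read_coordinates(file.path(DATA_DIR, "coords.csv"),
                                bounds = c(0, 20, 0, 20)),
       environment = read_environment(file.path(DATA_DIR, "environment.csv")))
}

cohort_subset <- function(dat, lab) {
  sel <- dat$genotypes$cohort == lab
  fr <- spatial_frame(dat$frame$ids[sel], dat$frame$x[sel], dat$frame$y[sel],
                      dat$frame$bounds)
  list(genotypes = subset_genotypes_public(dat$genotypes, sel), frame = fr,
       sel = sel)
}

# thin wrapper so the scripts do not reach into package internals
subset_genotypes_public <- function(g, keep) {
  keep <- which(keep)
  genotype_table(g$ids[keep], as.character(g$cohort)[keep],
                 g$calls[keep, , , drop = FALSE], g$loci,
                 haplotype = g$haplotype[keep])
}
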