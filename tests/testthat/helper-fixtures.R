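# Shared fixtures, built in code at test time.

# Genotype table with i.i.d. allele draws (no spatial or family structure).
iid_genotypes <- function(n, L = 5, A = 5, cohorts = c("2010", "2011")) {
  calls <- array(sample.int(A, n * L * 2, replace = TRUE), dim = c(n, L, 2))
  genotype_table(sprintf("i%03d", seq_len(n)),
                 rep(cohorts, length.out = n),
                 calls, sprintf("L%02d", seq_len(L)))
}

# Random spatial frame on a square plot.
random_frame <- function(n, side = 20) {
  spatial_frame(sprintf("i%03d", seq_len(n)),
                stats::runif(n, 0, side), stats::runif(n, 0, side),
                bounds = c(0, side, 0, side))
}

# Genotype table from an explicit list of "a/b" strings per locus.
calls_table <- function(geno_strings, cohort = NULL, haplotype = NULL) {
  n <- length(geno_strings)
  L <- length(strsplit(geno_strings[[1]], " ")[[1]])
  calls <- array(NA_integer_, dim = c(n, L, 2))
  for (i in seq_len(n)) {
    toks <- strsplit(geno_strings[[i]], " ")[[1]]
    for (l in seq_len(L)) {
      if (toks[l] == "NA") next
      ab <- as.integer(strsplit(toks[l], "/")[[1]])
      calls[i, l, ] <- ab
    }
  }
  genotype_table(sprintf("i%02d", seq_len(n)),
                 cohort %||% rep("2010", n),
                 calls, sprintf("L%02d", seq_len(L)),
                 haplotype = haplotype)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One small default simulation shared across test files (memoized).
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key = "default", config = NULL) {
  if (is.null(.sim_cache[[key]])) {
    config <- config %||% sim_config(n_per_cohort = 40,
                                     burn_in_generations = 10,
                                     rng_seed = 404)
    .sim_cache[[key]] <- simulate_cohorts(config)
  }
  .sim_cache[[key]]
}
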