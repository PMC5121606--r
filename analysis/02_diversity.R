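#!/usr/bin/env Rscript
# Per-locus diversity, Hardy-Weinberg tests, and inter-annual (between
# cohort) differentiation: Weir-Cockerham F_ST with permutations and a
# chord-distance AMOVA.
source("analysis/00_config.R")
dat <- load_study_data()
acfg <- study_analysis_config()
dir.create("results/diversity", showWarnings = FALSE, recursive = TRUE)
set.seed(stage_seed(MASTER_SEED, "diversity-script"))

summ <- locus_summaries(dat$genotypes)
summ$hwe_p <- NA_real_
for (r in seq_len(nrow(summ))) {
  if (is.na(summ$f_is[r])) next
  summ$hwe_p[r] <- hwe_test(dat$genotypes, summ$locus[r], summ$cohort[r],
                            n_perm = 999)$p_value
}
write.table(summ, "results/diversity/locus_summaries.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

fst <- fst_between_cohorts(dat$genotypes, n_perm = acfg$n_perm_fst)
amv <- amova_chord(dat$genotypes, n_perm = acfg$n_perm_fst)
jsonlite::write_json(
  list(fst = fst$fst, fst_p = fst$p_value,
       fst_per_locus = as.list(fst$fst_per_locus),
       amova_sigma2_among = amv$sigma2_among,
       amova_sigma2_among_raw = amv$sigma2_among_raw,
       amova_phi_st = amv$phi_st, amova_p = amv$p_value),
  "results/diversity/differentiation.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat(sprintf("Mean H_O = %.3f, mean H_E = %.3f over %d locus x cohort cells\n",
            mean(summ$h_obs, na.rm = TRUE), mean(summ$h_exp, na.rm = TRUE),
            nrow(summ)))
cat(sprintf("Loci out of HWE at alpha = 0.05: %d / %d\n",
            sum(summ$hwe_p < 0.05, na.rm = TRUE), sum(!is.na(summ$hwe_p))))
cat(sprintf("Between-cohort F_ST = %.4f (p = %.3f); AMOVA sigma2 = %.4f (p = %.3f)\n",
            fst$fst, fst$p_value, amv$sigma2_among, amv$p_value))
cat("Tables in results/diversity/\n")
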