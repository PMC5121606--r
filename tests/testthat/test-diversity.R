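test_that("heterozygosity, F_IS and allelic richness behave per locus and cohort", {
  # cohort of 4, all heterozygous A/B -> H_O = 1, F_IS < 0
  g <- calls_table(rep("1/2", 4))
  s <- locus_summaries(g)
  expect_equal(s$h_obs, 1)
  expect_lt(s$f_is, 0)
  expect_equal(s$allelic_richness, 2L)

  # hand-computed unbiased H_E on a 6-individual, 3-allele toy
  g6 <- calls_table(c("1/1", "1/2", "2/3", "3/3", "1/3", "2/2"))
  s6 <- locus_summaries(g6)
  cnt <- c(`1` = 4, `2` = 4, `3` = 4) / 12
  he_hand <- (12 / 11) * (1 - sum(cnt^2))
  expect_equal(s6$h_exp, he_hand, tolerance = 1e-12)
  expect_equal(s6$f_is, 1 - s6$h_obs / s6$h_exp, tolerance = 1e-12)

  # monomorphic locus: flagged, not an exception
  gm <- calls_table(c("1/1 1/2", "1/1 2/2", "1/1 1/1"))
  sm <- locus_summaries(gm)
  expect_equal(sm$h_exp[sm$locus == "L01"], 0)
  expect_true(is.na(sm$f_is[sm$locus == "L01"]))

  # F_IS identity holds on arbitrary data
  set.seed(2)
  sr <- locus_summaries(iid_genotypes(30))
  ok <- !is.na(sr$f_is)
  expect_equal(sr$f_is[ok], 1 - sr$h_obs[ok] / sr$h_exp[ok], tolerance = 1e-12)
})

test_that("HWE Monte-Carlo test accepts equilibrium and rejects homozygote excess", {
  # genotype counts exactly at Hardy-Weinberg proportions: 4 AA, 8 AB, 4 BB
  g <- calls_table(c(rep("1/1", 4), rep("1/2", 8), rep("2/2", 4)))
  set.seed(5)
  res <- hwe_test(g, "L01", "2010", n_perm = 499)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_gt(res$p_value, 0.5)

  # maximal heterozygote deficit: only AA and BB, n = 20
  g2 <- calls_table(c(rep("1/1", 10), rep("2/2", 10)))
  set.seed(6)
  res2 <- hwe_test(g2, "L01", "2010", n_perm = 999)
  expect_lte(res2$p_value, 0.01)

  expect_error(hwe_test(calls_table(rep("NA", 3)), "L01", "2010"), "missing")
})

test_that("HWE Monte-Carlo p matches exhaustive enumeration of allele pairings", {
  # n = 5 diploids, 2 alleles: 945 perfect matchings of the 10 allele copies
  geno <- c("1/1", "1/2", "1/2", "2/2", "2/2")
  g <- calls_table(geno)
  copies <- unlist(lapply(strsplit(geno, "/"), as.integer))

  pairings <- function(items) {
    if (length(items) == 0L) return(list(integer(0)))
    out <- list()
    for (j in 2:length(items)) {
      rest <- pairings(items[-c(1L, j)])
      out <- c(out, lapply(rest, function(r) c(items[1L], items[j], r)))
    }
    out
  }
  chisq_hand <- function(v) {
    a <- v[seq(1, length(v), 2)]; b <- v[seq(2, length(v), 2)]
    n <- length(a)
    p1 <- sum(c(a, b) == 1) / (2 * n)
    e11 <- n * p1^2; e22 <- n * (1 - p1)^2; e12 <- 2 * n * p1 * (1 - p1)
    o11 <- sum(a == 1 & b == 1); o22 <- sum(a == 2 & b == 2)
    o12 <- n - o11 - o22
    sum((c(o11, o12, o22) - c(e11, e12, e22))^2 / c(e11, e12, e22))
  }
  null_exact <- vapply(pairings(copies), chisq_hand, 0)
  expect_length(null_exact, 945L)
  obs <- chisq_hand(as.vector(t(cbind(g$calls[, 1, 1], g$calls[, 1, 2]))))
  p_exact <- mean(null_exact >= obs)

  set.seed(7)
  n_perm <- 4999
  res <- hwe_test(g, "L01", "2010", n_perm = n_perm)
  expect_equal(res$statistic, obs, tolerance = 1e-12)
  mc_se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(res$p_value - p_exact), 3 * mc_se + 2 / n_perm)
})

test_that("Weir-Cockerham theta matches an independent transcription and its limits", {
  # independent, loop-heavy transcription of the 1984 estimator
  wc_hand <- function(g) {
    A <- 0; BB <- 0; CC <- 0
    for (l in seq_along(g$loci)) {
      a1 <- g$calls[, l, 1]; a2 <- g$calls[, l, 2]
      sc <- !is.na(a1)
      pops <- levels(g$cohort)
      n_i <- sapply(pops, function(p) sum(sc & g$cohort == p))
      r <- 2; nbar <- mean(n_i)
      nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
      for (al in unique(c(a1[sc], a2[sc]))) {
        p_i <- h_i <- numeric(r)
        for (k in 1:2) {
          w <- sc & g$cohort == pops[k]
          p_i[k] <- (sum(a1[w] == al) + sum(a2[w] == al)) / (2 * n_i[k])
          h_i[k] <- sum((a1[w] == al) != (a2[w] == al)) / n_i[k]
        }
        pbar <- sum(n_i * p_i) / (r * nbar)
        s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
        hbar <- sum(n_i * h_i) / (r * nbar)
        A <- A + (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
        BB <- BB + (nbar / (nbar - 1)) *
          (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
        CC <- CC + hbar / 2
      }
    }
    A / (A + BB + CC)
  }
  g <- calls_table(c("1/2 1/1 2/3", "1/1 1/2 3/3", "2/2 2/2 1/3",
                     "1/2 1/2 1/1", "2/2 1/1 1/2", "1/1 2/2 2/3"),
                   cohort = rep(c("2010", "2011"), each = 3))
  set.seed(8)
  res <- fst_between_cohorts(g, n_perm = 49)
  expect_equal(res$fst, wc_hand(g), tolerance = 1e-10)

  # maximal differentiation: cohorts fixed for different alleles
  # (large enough that no label permutation reproduces the split)
  gfix <- calls_table(c(rep("1/1 1/1", 12), rep("2/2 2/2", 12)),
                      cohort = rep(c("2010", "2011"), each = 12))
  set.seed(9)
  rfix <- fst_between_cohorts(gfix, n_perm = 500)
  expect_equal(rfix$fst, 1, tolerance = 1e-12)
  expect_lte(rfix$p_value, 0.002)

  # null case: both cohorts from one pool -> theta near 0
  set.seed(10)
  gn <- iid_genotypes(100, L = 5, A = 8)
  rn <- fst_between_cohorts(gn, n_perm = 49)
  expect_lt(abs(rn$fst), 0.02)

  # invariance to individual ordering
  set.seed(11)
  ord <- sample(length(gn$ids))
  gshuf <- genotype_table(gn$ids[ord], as.character(gn$cohort)[ord],
                          gn$calls[ord, , , drop = FALSE], gn$loci)
  expect_equal(fst_between_cohorts(gshuf, n_perm = 1)$fst, rn$fst,
               tolerance = 1e-12)
})

test_that("chord-distance AMOVA components match the Gower matrix-algebra oracle", {
  # identical genotypes -> zero chord distance
  g0 <- calls_table(c("1/2 3/3", "1/2 3/3"))
  expect_equal(chord_distances(g0)[1, 2], 0, tolerance = 1e-12)

  # duplicating every individual into both cohorts -> sigma2_among = 0
  strs <- c("1/2 1/3", "2/2 3/3", "1/1 1/2")
  gd <- calls_table(rep(strs, 2), cohort = rep(c("2010", "2011"), each = 3))
  set.seed(12)
  ad <- amova_chord(gd, n_perm = 49)
  expect_equal(ad$sigma2_among, 0)
  expect_lte(ad$sigma2_among_raw, 1e-12)

  # 6-individual toy vs. brute-force ANOVA on the Gower-centered matrix
  g6 <- calls_table(c("1/2 1/1", "1/1 2/3", "2/2 1/3",
                      "1/2 2/2", "2/3 1/1", "3/3 1/2"),
                    cohort = rep(c("2010", "2011"), each = 3))
  set.seed(13)
  a6 <- amova_chord(g6, n_perm = 99)
  D2 <- chord_distances(g6)^2
  gower_ss <- function(M) {
    n <- nrow(M); H <- diag(n) - matrix(1 / n, n, n)
    sum(diag(-0.5 * H %*% M %*% H))
  }
  ss_tot <- gower_ss(D2)
  ss_within <- gower_ss(D2[1:3, 1:3]) + gower_ss(D2[4:6, 4:6])
  ss_among <- ss_tot - ss_within
  ms_among <- ss_among / 1; ms_within <- ss_within / 4
  n0 <- (6 - (9 + 9) / 6) / 1
  expect_equal(a6$ss[["among"]], ss_among, tolerance = 1e-10)
  expect_equal(a6$sigma2_within, ms_within, tolerance = 1e-10)
  expect_equal(a6$sigma2_among_raw, (ms_among - ms_within) / n0,
               tolerance = 1e-10)
})
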