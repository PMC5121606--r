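test_that("kinship has the expected sign structure at a balanced biallelic locus", {
  # reference sample engineered to p = (0.5, 0.5): 10 AA, 10 BB, 20 AB
  g <- calls_table(c(rep("1/1", 10), rep("2/2", 10), rep("1/2", 20)))
  k <- kinship_matrix(g)
  # identical homozygotes at even frequencies: ~1 + O(1/n) correction
  expect_gt(k$values[1, 2], 1)
  expect_lt(k$values[1, 2], 1.1)
  # opposite homozygotes: negative
  expect_lt(k$values[1, 11], 0)
  # heterozygote vs itself-like pair: intermediate
  expect_true(is.na(k$values[1, 1]))  # diagonal excluded
})

test_that("kinship equals a literal term-by-term transcription of the estimator", {
  g <- calls_table(c("1/2 3/3", "1/1 1/3", "2/2 NA", "1/2 1/1", "2/2 3/1"))
  k <- kinship_matrix(g)

  # independent transcription: explicit loops over loci, alleles, pairs
  n <- 5
  hand <- matrix(NA_real_, n, n)
  num_tot <- matrix(0, n, n); den_tot <- matrix(0, n, n)
  for (l in 1:2) {
    a1 <- g$calls[, l, 1]; a2 <- g$calls[, l, 2]
    sc <- which(!is.na(a1))
    alleles <- sort(unique(c(a1[sc], a2[sc])))
    nl <- length(sc)
    p <- sapply(alleles, function(a) sum(c(a1[sc], a2[sc]) == a) / (2 * nl))
    den <- sum(p * (1 - p))
    for (i in sc) for (j in sc) {
      if (i == j) next
      s <- 0
      for (ai in seq_along(alleles)) {
        pia <- ((a1[i] == alleles[ai]) + (a2[i] == alleles[ai])) / 2
        pja <- ((a1[j] == alleles[ai]) + (a2[j] == alleles[ai])) / 2
        s <- s + (pia - p[ai]) * (pja - p[ai]) +
          p[ai] * (1 - p[ai]) / (2 * nl - 1)  # 2 n_l - 1 gene copies minus one
      }
      num_tot[i, j] <- num_tot[i, j] + s
      den_tot[i, j] <- den_tot[i, j] + den
    }
  }
  hand <- ifelse(den_tot > 0, num_tot / den_tot, NA_real_)
  diag(hand) <- NA_real_
  expect_equal(unname(k$values), hand, tolerance = 1e-12)
  # pair with a missing locus uses only the shared locus
  expect_equal(k$values[1, 3], k$per_locus[1, 3, 1], tolerance = 1e-12)
})

test_that("mean pairwise kinship is centered at zero for unstructured samples", {
  set.seed(21)
  means <- vapply(1:50, function(s) {
    g <- iid_genotypes(30, L = 5, A = 6)
    v <- kinship_matrix(g)$values
    mean(v[upper.tri(v)], na.rm = TRUE)
  }, 0)
  expect_lt(abs(mean(means)), 3 * stats::sd(means) / sqrt(50))
})

test_that("the haploid path matches the diploid path on doubled homozygotes", {
  set.seed(22)
  hap <- sample(1:4, 12, replace = TRUE)
  g_h <- genotype_table(sprintf("i%02d", 1:12), rep("2010", 12),
                        array(1L, dim = c(12, 1, 2)), "dummy",
                        haplotype = hap)
  k_h <- kinship_matrix(g_h, marker = "plastid")
  calls <- array(rep(hap, 2), dim = c(12, 1, 2))
  g_d <- genotype_table(sprintf("i%02d", 1:12), rep("2010", 12), calls, "L01")
  k_d <- kinship_matrix(g_d, marker = "ssr")
  # identical cross-product terms; the two paths differ only by the
  # small-sample constant (n vs. 2n gene copies in the bias correction)
  delta <- k_h$values - k_d$values
  off <- delta[upper.tri(delta)]
  expect_lt(diff(range(off)), 1e-12)
  den <- sum(k_h$freqs[[1]] * (1 - k_h$freqs[[1]]))
  expect_equal(off[1], (den / 11 - den / 23) / den, tolerance = 1e-12)
})

test_that("reordering individuals permutes the kinship matrix consistently", {
  set.seed(23)
  g <- iid_genotypes(10)
  k <- kinship_matrix(g)
  ord <- sample(10)
  g2 <- genotype_table(g$ids[ord], as.character(g$cohort)[ord],
                       g$calls[ord, , , drop = FALSE], g$loci)
  k2 <- kinship_matrix(g2)
  expect_equal(k2$values[g$ids, g$ids], k$values[g$ids, g$ids],
               tolerance = 1e-12)
})
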