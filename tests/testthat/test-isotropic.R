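test_that("a single distance class reproduces the grand mean kinship with p near 1", {
  set.seed(31)
  g <- iid_genotypes(12, cohorts = "2010")
  fr <- random_frame(12, side = 0.4)   # every pair closer than one class width
  k <- kinship_matrix(g)
  geom <- pairwise_geometry(fr)
  cfg <- analysis_config(n_perm_distogram = 199, rng_seed = 31)
  d <- distogram(k, geom$dist, "within", "2010", cfg)
  expect_equal(nrow(d), 1L)
  expect_equal(d$F_D[1], mean(k$values[upper.tri(k$values)], na.rm = TRUE),
               tolerance = 1e-12)
  expect_gt(d$p_value[1], 0.5)  # no spatial signal is possible
})

test_that("Sp is the documented function of its own slope and first-class kinship", {
  expect_equal(sp_coefficient(0, 0.4), 0)      # flat kinship -> Sp = 0
  sim <- cached_sim()
  k <- kinship_matrix(sim$genotypes)
  geom <- pairwise_geometry(sim$frame)
  cfg <- analysis_config(rng_seed = 32)
  sp <- sp_statistic(k, geom$dist, "within", "2010", cfg, n_perm = 19)
  expect_equal(sp$Sp, -sp$b_F / (1 - sp$F_1), tolerance = 1e-15)

  # the slope equals an lm fit on the same pairs
  pairs <- which(upper.tri(geom$dist), arr.ind = TRUE)
  keep <- sim$genotypes$cohort[pairs[, 1]] == "2010" &
    sim$genotypes$cohort[pairs[, 2]] == "2010" & geom$dist[pairs] > 0
  f <- k$values[pairs][keep]; dd <- geom$dist[pairs][keep]
  expect_equal(sp$b_F, unname(stats::coef(stats::lm(f ~ log(dd)))[2]),
               tolerance = 1e-10)
  expect_equal(sp$F_1,
               mean(k$values[pairs][geom$dist[pairs] < 0.5 &
                 sim$genotypes$cohort[pairs[, 1]] == "2010" &
                 sim$genotypes$cohort[pairs[, 2]] == "2010"]),
               tolerance = 1e-12)
})

test_that("jackknife-over-loci standard errors match the delete-one formula", {
  set.seed(33)
  g <- iid_genotypes(15, L = 3, A = 4, cohorts = "2010")
  fr <- random_frame(15)
  k <- kinship_matrix(g)
  geom <- pairwise_geometry(fr)
  cfg <- analysis_config(rng_seed = 33)
  sp <- sp_statistic(k, geom$dist, "within", "2010", cfg, n_perm = 9)

  loo <- sp$jackknife[, "Sp"]
  L <- 3
  se_hand <- sqrt((L - 1) / L * sum((loo - mean(loo))^2))
  expect_equal(sp$se_Sp, se_hand, tolerance = 1e-12)

  # each delete-one estimate reproduces an independent two-locus analysis
  for (l in 1:3) {
    g2 <- genotype_table(g$ids, as.character(g$cohort),
                         g$calls[, -l, , drop = FALSE], g$loci[-l])
    k2 <- kinship_matrix(g2)
    sp2 <- sp_statistic(k2, geom$dist, "within", "2010", cfg, n_perm = 1)
    expect_equal(unname(sp$jackknife[l, "Sp"]), sp2$Sp, tolerance = 1e-12)
  }
})

test_that("cohort comparison t-tests behave at the identity and at 3-sigma separation", {
  a <- structure(list(b_F = -0.01, F_1 = 0.05, Sp = 0.012,
                      se_bF = 0.001, se_F1 = 0.01, se_Sp = 0.001),
                 class = "sp_result")
  cmp <- compare_cohorts(a, a, n_loci = 10)
  expect_equal(cmp$t, rep(0, 3))
  expect_equal(cmp$p_value, rep(1, 3))

  b <- a
  b$Sp <- a$Sp + 3 * sqrt(2 * a$se_Sp^2)
  cmp2 <- compare_cohorts(a, b, n_loci = 10)
  expect_lt(cmp2$p_value[cmp2$parameter == "Sp"], 0.05)

  a_missing <- a; a_missing$se_Sp <- NA_real_
  expect_error(compare_cohorts(a_missing, b, 10), "SE")
})

test_that("permutation envelopes agree in sign decisions between 99 and 9999 draws", {
  sim <- cached_sim("tight", sim_config(n_per_cohort = 15, n_loci = 8,
                                        burn_in_generations = 10,
                                        rng_seed = 77))
  k <- kinship_matrix(sim$genotypes)
  geom <- pairwise_geometry(sim$frame)
  d_small <- distogram(k, geom$dist, "within", "2010",
                       analysis_config(n_perm_distogram = 99, rng_seed = 34))
  d_big <- distogram(k, geom$dist, "within", "2010",
                     analysis_config(n_perm_distogram = 9999, rng_seed = 34))
  clear <- which(!is.na(d_big$p_value) & d_big$p_value < 0.01 &
                   d_big$n_pairs >= 5)
  expect_gt(length(clear), 0L)
  for (ci in clear) {
    expect_lt(d_small$p_value[ci], 0.05)
    expect_equal(d_small$F_D[ci] > d_small$envelope_hi[ci],
                 d_big$F_D[ci] > d_big$envelope_hi[ci])
  }
})

test_that("the iterative distance-range restriction converges and restricts the slope", {
  sim <- cached_sim()
  k <- kinship_matrix(sim$genotypes)
  geom <- pairwise_geometry(sim$frame)
  cfg <- analysis_config(rng_seed = 35)
  dens <- length(sim$frame$ids) / 400  # individuals per m^2
  sp_full <- sp_statistic(k, geom$dist, "within", "2010", cfg, n_perm = 1)
  sp_rng <- sp_statistic(k, geom$dist, "within", "2010", cfg,
                         density = dens, n_perm = 1)
  if (sp_rng$range_restricted) {
    expect_gt(sp_rng$distance_range_used[1], 0)
    expect_lt(sp_rng$n_pairs_regression, sp_full$n_pairs_regression)
  } else {
    expect_equal(sp_rng$distance_range_used, sp_full$distance_range_used)
  }
})
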