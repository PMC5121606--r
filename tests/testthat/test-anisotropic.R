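test_that("bearing transform weights log-distance by squared cosine of angle offset", {
  d <- matrix(c(0, exp(1), exp(1), 0), 2)
  b <- matrix(c(NA, 45, 45, NA), 2)
  # pair aligned with theta, d = e -> T = 1
  expect_equal(bearing_transform(d, b, 45)[1, 2], 1, tolerance = 1e-12)
  # pair perpendicular to theta -> T = 0
  expect_equal(bearing_transform(d, b, 135)[1, 2], 0, tolerance = 1e-12)
  # zero-distance pairs are masked
  d0 <- matrix(0, 2, 2)
  expect_true(all(is.na(bearing_transform(d0, b, 10))))

  # 180-degree periodicity on a random configuration
  set.seed(41)
  fr <- random_frame(6)
  geo <- pairwise_geometry(fr)
  for (th in c(0, 33.3, 90)) {
    expect_equal(bearing_transform(geo$dist, geo$bearing, th),
                 bearing_transform(geo$dist, geo$bearing, th + 180),
                 tolerance = 1e-12)
  }
})

test_that("Mantel correlation and p match exhaustive enumeration on five points", {
  set.seed(42)
  fr <- random_frame(5)
  g <- iid_genotypes(5, L = 6, A = 4, cohorts = "2010")
  k <- kinship_matrix(g)
  geo <- pairwise_geometry(fr)
  cfg <- analysis_config(n_bearing_angles = 4, rng_seed = 42)
  bc <- bearing_correlogram(k, geo$dist, geo$bearing, cfg, exact = TRUE)

  # brute force: iterate over all 120 permutations with nested loops
  ut <- which(upper.tri(geo$dist), arr.ind = TRUE)
  angles <- c(0, 45, 90, 135)
  for (ai in seq_along(angles)) {
    Tv <- bearing_transform(geo$dist, geo$bearing, angles[ai])[ut]
    r_obs <- stats::cor(k$values[ut], Tv)
    null <- c()
    for (i1 in 1:5) for (i2 in 1:5) for (i3 in 1:5) for (i4 in 1:5) for (i5 in 1:5) {
      pm <- c(i1, i2, i3, i4, i5)
      if (length(unique(pm)) < 5) next
      null <- c(null, stats::cor(k$values[cbind(pm[ut[, 1]], pm[ut[, 2]])], Tv))
    }
    expect_length(null, 120L)
    p_exact <- min(1, 2 * min(mean(null >= r_obs), mean(null <= r_obs)))
    expect_equal(bc$profile$r[ai], r_obs, tolerance = 1e-12)
    expect_equal(bc$profile$p_value[ai], p_exact, tolerance = 1e-12)
  }
})

test_that("the per-angle statistic agrees with an established Mantel implementation", {
  skip_if_not_installed("vegan")
  set.seed(46)
  fr <- random_frame(12)
  g <- iid_genotypes(12, L = 6, A = 4, cohorts = "2010")
  k <- kinship_matrix(g)
  geo <- pairwise_geometry(fr)
  cfg <- analysis_config(n_bearing_angles = 4, n_perm_mantel = 49,
                         rng_seed = 46)
  bc <- bearing_correlogram(k, geo$dist, geo$bearing, cfg)
  kv <- k$values; diag(kv) <- 0
  for (ai in 1:4) {
    Tm <- bearing_transform(geo$dist, geo$bearing, bc$profile$angle[ai])
    vm <- vegan::mantel(stats::as.dist(kv), stats::as.dist(Tm),
                        permutations = 0)
    expect_equal(bc$profile$r[ai], unname(vm$statistic), tolerance = 1e-10)
  }
})

test_that("the correlogram is invariant to adding 180 degrees to every bearing", {
  sim <- cached_sim()
  sel <- sim$genotypes$cohort == "2010"
  k <- kinship_matrix(subset_genotypes(sim$genotypes, sel))
  fr <- spatial_frame(sim$frame$ids[sel], sim$frame$x[sel], sim$frame$y[sel],
                      sim$frame$bounds)
  geo <- pairwise_geometry(fr)
  cfg <- analysis_config(n_bearing_angles = 16, n_perm_mantel = 49,
                         rng_seed = 43)
  b1 <- bearing_correlogram(k, geo$dist, geo$bearing, cfg)
  b2 <- bearing_correlogram(k, geo$dist, (geo$bearing + 180) %% 360, cfg)
  expect_equal(b1$profile$r, b2$profile$r, tolerance = 1e-10)
  # identical seed -> identical p profile (shared permutations across angles)
  b3 <- bearing_correlogram(k, geo$dist, geo$bearing, cfg)
  expect_identical(b1$profile$p_value, b3$profile$p_value)
})

test_that("a 90-degree sector reproduces the full isotropic analysis", {
  sim <- cached_sim()
  k <- kinship_matrix(sim$genotypes)
  geo <- pairwise_geometry(sim$frame)
  cfg <- analysis_config(sector_halfwidth = 90, rng_seed = 44)
  full <- sp_statistic(k, geo$dist, "within", "2010", cfg, n_perm = 1)
  sect <- sector_sp(k, geo$dist, geo$bearing, 57, "within", "2010", cfg,
                    n_perm = 1)
  expect_equal(sect$b_F, full$b_F, tolerance = 1e-12)
  expect_equal(sect$F_1, full$F_1, tolerance = 1e-12)
  expect_equal(sect$Sp, full$Sp, tolerance = 1e-12)
  expect_equal(sect$se_Sp, full$se_Sp, tolerance = 1e-12)
  expect_equal(sect$n_pairs, full$n_pairs)
})

test_that("sector membership counts pairs by angular distance on the half-circle", {
  fr <- spatial_frame(letters[1:6], c(0, 0, 1, 2, 3, 5), c(0, 1, 0, 2, 1, 4))
  g <- iid_genotypes(6, cohorts = "2010")
  k <- kinship_matrix(g)
  geo <- pairwise_geometry(fr)
  cfg <- analysis_config(sector_halfwidth = 15, rng_seed = 45)
  theta <- 170
  hand <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    a <- geo$bearing[i, j]
    dd <- abs(a - theta) %% 180
    if (min(dd, 180 - dd) <= 15) hand <- hand + 1
  }
  if (hand >= 2) {
    sect <- sector_sp(k, geo$dist, geo$bearing, theta, "within", "2010", cfg,
                      n_perm = 1)
    expect_equal(sect$n_pairs, hand)
  } else {
    expect_error(sector_sp(k, geo$dist, geo$bearing, theta, "within", "2010",
                           cfg, n_perm = 1), "sector")
  }
})
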