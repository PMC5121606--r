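test_that("environmental PCA predictors are standardized, anchored and eigen-consistent", {
  set.seed(61)
  n <- 12
  env <- environment_table(data.frame(
    individual_id = sprintf("i%02d", 1:n),
    dsf = runif(n), na = rnorm(n, 5), k = rnorm(n, 2), mg = rnorm(n, 1),
    n_total = rnorm(n, 0.3, 0.05), p_total = rnorm(n, 0.05, 0.01),
    field_capacity = runif(n, 0.1, 0.4)))
  ep <- build_env_predictors(env)
  for (v in names(ep$predictors)) {
    expect_equal(mean(ep$predictors[[v]]), 0, tolerance = 1e-12)
    expect_equal(stats::sd(ep$predictors[[v]]), 1, tolerance = 1e-12)
  }
  # sign anchoring: dominant loading positive on every component
  for (j in 1:ncol(ep$loadings$cations))
    expect_gt(max(ep$loadings$cations[, j]), 0)

  # perfectly correlated anions -> PC1 explains 100%
  env2 <- env
  env2$p_total <- 2 * env2$n_total + 1
  ep2 <- build_env_predictors(environment_table(as.data.frame(env2)))
  expect_equal(ep2$variance_explained$anions[1], 1, tolerance = 1e-12)

  # independent eigendecomposition oracle for the cation scores
  M <- scale(as.data.frame(env)[c("na", "k", "mg")])
  ev <- eigen(stats::cor(M))
  sc1 <- M %*% ev$vectors[, 1]
  r <- stats::cor(sc1, ep$predictors$cations1)
  expect_equal(abs(r[1]), 1, tolerance = 1e-10)

  env3 <- env; env3$mg <- 1
  expect_error(build_env_predictors(environment_table(as.data.frame(env3))), "mg")
})

test_that("the SAR fit reduces to OLS without spatial weights", {
  set.seed(62)
  n <- 30
  X <- cbind(a = rnorm(n), b = rnorm(n))
  G <- 1 + 0.5 * X[, "a"] + rnorm(n)
  net <- structure(list(W = matrix(0, n, n), style = "raw",
                        ids = as.character(1:n)), class = "connection_network")
  f <- sar_fit(G, X, net)
  expect_equal(f$rho, 0)
  ols <- stats::lm(G ~ X)
  expect_equal(unname(f$beta), unname(stats::coef(ols)), tolerance = 1e-10)
  expect_equal(f$sigma2, sum(stats::residuals(ols)^2) / n, tolerance = 1e-12)
})

test_that("the profile-likelihood optimum beats a 101-point grid scan", {
  set.seed(63)
  n <- 40
  fr <- random_frame(n)
  net <- build_network(fr, "row", k = 6)
  X <- cbind(a = rnorm(n))
  A <- diag(n) - 0.6 * net$W
  G <- drop(solve(A, 0.5 * X + rnorm(n)))
  f <- sar_fit(G, X, net)
  lam <- f$eigenvalues
  Xi <- cbind(1, X)
  prof <- function(rho) {
    z <- G - rho * drop(net$W %*% G)
    rss <- sum(stats::lm.fit(Xi, z)$residuals^2)
    sum(log(1 - rho * lam)) - n / 2 * (log(2 * pi * rss / n) + 1)
  }
  grid <- seq(1 / min(lam) * 0.999, 0.999, length.out = 101)
  expect_gte(f$loglik + 1e-8, max(sapply(grid, prof)))
  # the reported loglik is the profile loglik at the optimum
  expect_equal(f$loglik, prof(f$rho), tolerance = 1e-8)
  expect_error(sar_fit(G, X, build_network(fr, "raw")), "row-standardized")
})

test_that("SAR fitting absorbs spatial autocorrelation out of the residuals", {
  set.seed(64)
  n <- 60
  fr <- random_frame(n)
  net <- build_network(fr, "row", k = 6)
  A <- diag(n) - 0.9 * net$W
  X <- cbind(a = rnorm(n))
  G <- drop(solve(A, rnorm(n)))
  f <- sar_fit(G, X, net)
  expect_lt(abs(f$residual_moran_i), abs(moran_i(G, net$W)))
  rm <- residual_moran_test(f, net, n_perm = 99)
  expect_equal(rm$I, f$residual_moran_i, tolerance = 1e-12)
})

test_that("model averaging keeps rho structural and is invariant to predictor order", {
  set.seed(65)
  n <- 50
  fr <- random_frame(n)
  net <- build_network(fr, "row", k = 6)
  P <- as.data.frame(matrix(rnorm(n * 5), n,
                            dimnames = list(NULL, c("dsf", "anions",
                                                    "cations1", "cations2",
                                                    "field_capacity"))))
  A <- diag(n) - 0.5 * net$W
  G <- drop(solve(A, 1 + 1.2 * P$dsf + rnorm(n, sd = 0.7)))
  ma <- model_select_average(G, P, net, n_perm_moran = 9)
  expect_equal(ma$rho$w_plus, 1)
  expect_equal(nrow(ma$models), 32L)
  expect_true(all(ma$table$w_plus >= 0 & ma$table$w_plus <= 1))
  # the predictor truly in the model dominates
  expect_equal(ma$table$predictor[which.max(ma$table$w_plus)], "dsf")

  ma2 <- model_select_average(G, P[, c(3, 1, 5, 2, 4)], net, n_perm_moran = 9)
  expect_equal(sort(ma$models$aic), sort(ma2$models$aic), tolerance = 1e-8)
  t1 <- ma$table[order(ma$table$predictor), ]
  t2 <- ma2$table[order(ma2$table$predictor), ]
  expect_equal(t1$w_plus, t2$w_plus, tolerance = 1e-6)
  expect_equal(t1$estimate, t2$estimate, tolerance = 1e-6)

  # full averaging shrinks relative to conditional averaging
  mc <- model_select_average(G, P, net, average = "conditional",
                             n_perm_moran = 9)
  weak <- setdiff(ma$table$predictor, "dsf")
  i_f <- match(weak, ma$table$predictor)
  i_c <- match(weak, mc$table$predictor)
  ok <- !is.na(mc$table$estimate[i_c])
  expect_gt(sum(ok), 0)
  expect_true(all(abs(ma$table$estimate[i_f][ok]) <=
                    abs(mc$table$estimate[i_c][ok]) + 1e-12))
})
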