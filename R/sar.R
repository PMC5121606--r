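#' Environmental predictor set via PCA dimension reduction
#'
#' Runs a correlation-matrix PCA over the soil cations (Na, K, Mg), keeping
#' the first two components (`cations1`, `cations2`), and over the anions
#' (total N, P), keeping the first (`anions`); light availability (DSF) and
#' field capacity are standardized directly. PCA signs are anchored so the
#' variable with the largest absolute loading on each component loads
#' positively, making runs reproducible. All predictors leave with mean 0
#' and SD 1.
#'
#' @param env an [environment_table()] (complete cases required).
#' @return A list of class `env_predictors`: `predictors` (data.frame of
#'   standardized `dsf`, `anions`, `cations1`, `cations2`,
#'   `field_capacity`), `loadings`, `variance_explained`, `ids`.
#' @export
build_env_predictors <- function(env) {
  df <- as.data.frame(env)
  vars <- c("dsf", "na", "k", "mg", "n_total", "p_total", "field_capacity")
  if (anyNA(df[vars])) stop("missing environmental values; complete cases required")
  if (nrow(df) < 3L) stop("need >= 3 individuals")
  for (v in vars)
    if (stats::sd(df[[v]]) == 0) stop("constant environmental variable: ", v)

  anchored_pca <- function(M) {
    p <- stats::prcomp(M, center = TRUE, scale. = TRUE)
    for (j in seq_len(ncol(p$rotation))) {
      top <- which.max(abs(p$rotation[, j]))
      if (p$rotation[top, j] < 0) {
        p$rotation[, j] <- -p$rotation[, j]
        p$x[, j] <- -p$x[, j]
      }
    }
    p
  }
  cat_pca <- anchored_pca(df[c("na", "k", "mg")])
  an_pca <- anchored_pca(df[c("n_total", "p_total")])
  std <- function(v) (v - mean(v)) / stats::sd(v)
  pred <- data.frame(
    dsf = std(df$dsf),
    anions = std(an_pca$x[, 1L]),
    cations1 = std(cat_pca$x[, 1L]),
    cations2 = std(cat_pca$x[, 2L]),
    field_capacity = std(df$field_capacity))
  structure(list(
    predictors = pred,
    loadings = list(cations = cat_pca$rotation, anions = an_pca$rotation),
    variance_explained = list(
      cations = cat_pca$sdev^2 / sum(cat_pca$sdev^2),
      anions = an_pca$sdev^2 / sum(an_pca$sdev^2)),
    ids = df$individual_id), class = "env_predictors")
}

#' Spatially lagged simultaneous autoregressive model by maximum likelihood
#'
#' Fits `G = rho W G + X beta + eps`, `eps ~ N(0, sigma2 I)`, with `W` a
#' row-standardized spatial weights matrix. Estimation profiles the
#' likelihood over `rho`: for a trial `rho`, `beta` is the least-squares
#' fit of `(I - rho W) G` on `X` and `sigma2 = RSS / n`; the log-likelihood
#' adds the Jacobian `log|I - rho W| = sum log(1 - rho lambda_i)` over the
#' eigenvalues of `W`. `rho` is maximized by bounded 1-D optimization
#' (tolerance 1e-8) on the admissible interval `(1/lambda_min, 1)`. An
#' all-zero `W` is accepted and reduces the fit to OLS with `rho = 0`.
#'
#' @param G numeric response vector (e.g. an sPCA score).
#' @param X predictor matrix or data.frame (an intercept column is added).
#' @param net a row-standardized [build_network()] (or zero matrix).
#' @return A list of class `sar_fit`: `rho`, `beta`, `beta_se`, `sigma2`,
#'   `loglik`, `aic`, `residuals`, `fitted`, plus `residual_moran_i` and
#'   `residual_moran_p` (permutation).
#' @export
sar_fit <- function(G, X, net) {
  W <- net$W
  n <- length(G)
  if (nrow(W) != n) stop("weights matrix does not match response length")
  zero_W <- all(W == 0)
  if (!zero_W && net$style != "row")
    stop("SAR requires a row-standardized network (style = 'row')")
  X <- as.matrix(cbind(`(Intercept)` = 1, X))
  if (qr(X)$rank < ncol(X)) stop("singular predictor matrix")
  if (n <= ncol(X) + 1L) stop("too few observations for predictors")

  WG <- drop(W %*% G)
  fit_beta <- function(rho) {
    z <- G - rho * WG
    fit <- stats::lm.fit(X, z)
    rss <- sum(fit$residuals^2)
    list(beta = fit$coefficients, sigma2 = rss / n, resid = fit$residuals)
  }

  if (zero_W) {
    rho_hat <- 0
    lambda <- rep(0, n)
  } else {
    # W = D^{-1} A with A symmetric: spectrum is real (similar to a
    # symmetric matrix); tiny imaginary parts are numerical noise
    lambda <- eigen(W, only.values = TRUE)$values
    if (is.complex(lambda)) {
      if (max(abs(Im(lambda))) > 1e-6)
        warning("discarding non-negligible imaginary parts of W eigenvalues")
      lambda <- Re(lambda)
    }
    lo <- 1 / min(lambda); hi <- 1 / max(lambda)
    prof <- function(rho) {
      f <- fit_beta(rho)
      sum(log(1 - rho * lambda)) - n / 2 * (log(2 * pi * f$sigma2) + 1)
    }
    opt <- stats::optimize(prof, interval = c(lo * (1 - 1e-9), hi * (1 - 1e-9)),
                           maximum = TRUE, tol = 1e-8)
    rho_hat <- opt$maximum
  }
  f <- fit_beta(rho_hat)
  ll <- sum(log(1 - rho_hat * lambda)) -
    n / 2 * (log(2 * pi * f$sigma2) + 1)
  k <- ncol(X) + 2L  # betas (incl. intercept) + rho + sigma2
  aic <- -2 * ll + 2 * k
  beta_cov <- f$sigma2 * solve(crossprod(X))
  res <- f$resid
  rmi <- if (zero_W) NA_real_ else moran_i(res, W)
  structure(list(rho = rho_hat, beta = f$beta,
                 beta_se = sqrt(diag(beta_cov)),
                 sigma2 = f$sigma2, loglik = ll, aic = aic, k = k, n = n,
                 residuals = res, fitted = G - res,
                 residual_moran_i = rmi,
                 eigenvalues = lambda), class = "sar_fit")
}

#' Permutation test of residual Moran's I for a SAR fit
#' @param fit a [sar_fit()].
#' @param net the network used in the fit.
#' @param n_perm permutations of the residual vector.
#' @return A list with `I` and `p_value` (two-sided).
#' @export
residual_moran_test <- function(fit, net, n_perm = 199L) {
  e <- fit$residuals
  obs <- moran_i(e, net$W)
  null <- vapply(seq_len(n_perm), function(b) moran_i(sample(e), net$W), 0)
  list(I = obs, p_value = perm_p_two_sided(null, obs))
}

#' All-subsets SAR model selection with Burnham-Anderson averaging
#'
#' Fits the lagged SAR model for every subset of the five environmental
#' predictors (32 models, always with intercept and the spatial lag term),
#' computes Akaike weights, keeps the models with `delta AIC < 2` from the
#' best, renormalizes their weights, and reports model-averaged
#' coefficients, unconditional standard errors and relative importance
#' `w+` per predictor. The spatial lag coefficient `rho` has `w+ = 1` by
#' construction (a structural parameter present in every model). With
#' `average = "full"` absent predictors contribute zero to the average
#' (shrinkage); `"conditional"` averages only over models containing the
#' predictor.
#'
#' @param G response vector (sPCA score).
#' @param env an [build_env_predictors()] result (or a data.frame of
#'   standardized predictors).
#' @param net row-standardized [build_network()].
#' @param average `"full"` or `"conditional"`.
#' @param weights_over `"selected"` (renormalized over the delta AIC < 2
#'   set) or `"all"` (all 32 models).
#' @param n_perm_moran permutations for residual Moran's I per selected
#'   model.
#' @return A list of class `model_average`: `table` (per-predictor averaged
#'   estimate, unconditional SE, `w+`), `rho` (weighted average and SE),
#'   `models` (per-model AIC table), `residual_moran` per selected model.
#' @export
model_select_average <- function(G, env, net,
                                 average = c("full", "conditional"),
                                 weights_over = c("selected", "all"),
                                 n_perm_moran = 199L) {
  average <- match.arg(average)
  weights_over <- match.arg(weights_over)
  P <- if (inherits(env, "env_predictors")) env$predictors else as.data.frame(env)
  pnames <- colnames(P)
  np <- length(pnames)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), np))
  colnames(subsets) <- pnames

  fits <- vector("list", nrow(subsets))
  for (m in seq_len(nrow(subsets))) {
    sel <- pnames[unlist(subsets[m, ])]
    Xm <- if (length(sel)) P[sel] else P[0]
    fits[[m]] <- tryCatch(sar_fit(G, Xm, net), error = function(e) {
      warning("model ", m, " dropped: ", conditionMessage(e)); NULL
    })
  }
  ok <- !vapply(fits, is.null, TRUE)
  aic <- vapply(fits[ok], `[[`, 0, "aic")
  midx <- which(ok)
  delta <- aic - min(aic)
  w_all <- exp(-delta / 2); w_all <- w_all / sum(w_all)
  sel_set <- delta < 2
  w_sel <- if (weights_over == "selected") {
    w <- ifelse(sel_set, w_all, 0); w / sum(w)
  } else w_all
  use <- if (weights_over == "selected") which(sel_set) else seq_along(midx)

  tab <- lapply(pnames, function(p) {
    in_model <- vapply(use, function(u) p %in% names(fits[[midx[u]]]$beta), TRUE)
    b <- vapply(use, function(u) {
      f <- fits[[midx[u]]]
      if (p %in% names(f$beta)) f$beta[[p]] else 0
    }, 0)
    s <- vapply(use, function(u) {
      f <- fits[[midx[u]]]
      if (p %in% names(f$beta)) f$beta_se[[p]] else 0
    }, 0)
    w <- w_sel[use]
    wplus <- sum(w[in_model])
    if (average == "conditional") {
      if (!any(in_model)) return(data.frame(
        predictor = p, estimate = NA_real_, se = NA_real_, w_plus = wplus))
      wc <- w[in_model] / sum(w[in_model])
      est <- sum(wc * b[in_model])
      se <- sum(wc * sqrt(s[in_model]^2 + (b[in_model] - est)^2))
    } else {
      est <- sum(w * b)
      se <- sum(w * sqrt(s^2 + (b - est)^2))
    }
    data.frame(predictor = p, estimate = est, se = se, w_plus = wplus,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tab)

  rho_vals <- vapply(use, function(u) fits[[midx[u]]]$rho, 0)
  w <- w_sel[use]
  rho_avg <- sum(w * rho_vals)
  rho_se <- sum(w * sqrt(0 + (rho_vals - rho_avg)^2))  # between-model spread

  models <- data.frame(
    model = vapply(midx, function(m)
      paste(pnames[unlist(subsets[m, ])], collapse = "+"), ""),
    k = vapply(fits[midx], `[[`, 0L, "k"),
    aic = aic, delta_aic = delta, weight = w_all,
    selected = sel_set, stringsAsFactors = FALSE)
  models$model[models$model == ""] <- "(intercept only)"

  rmoran <- lapply(which(sel_set), function(u)
    residual_moran_test(fits[[midx[u]]], net, n_perm_moran))
  names(rmoran) <- models$model[sel_set]

  structure(list(table = tab,
                 rho = list(estimate = rho_avg, se = rho_se, w_plus = 1),
                 models = models[order(models$delta_aic), ],
                 residual_moran = rmoran,
                 average = average, weights_over = weights_over,
                 fits = fits[midx]),
            class = "model_average")
}

#' @export
print.model_average <- function(x, ...) {
  cat(sprintf("model_average (%s averaging, weights over %s models)\n",
              x$average, x$weights_over))
  cat(sprintf("  rho: %.3f (w+ = 1); %d/%d models selected (delta AIC < 2)\n",
              x$rho$estimate, sum(x$models$selected), nrow(x$models)))
  print(x$table, row.names = FALSE)
  invisible(x)
}
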