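# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage name to an integer seed
#' below 2^31, so that adding a stage to a pipeline never perturbs the random
#' draws of another stage.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return A single integer seed.
#' @export
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) * 48271 + h * 69621) %% 2147483563) + 1L
}

# (1 + hits) / (1 + n) permutation p-value; never exactly 0.
perm_pval <- function(hits, n_perm) (1 + hits) / (1 + n_perm)

# Two-sided permutation p from a null vector and an observed value. Ties are
# resolved with a small relative tolerance so that null draws equal to the
# observed value up to floating-point noise count as ties on both sides.
perm_p_two_sided <- function(null, obs) {
  null <- null[is.finite(null)]
  n <- length(null)
  eps <- 1e-10 * max(1, abs(obs))
  p_hi <- perm_pval(sum(null >= obs - eps), n)
  p_lo <- perm_pval(sum(null <= obs + eps), n)
  min(1, 2 * min(p_hi, p_lo))
}

# One-sided (greater) permutation p.
perm_p_greater <- function(null, obs) {
  null <- null[is.finite(null)]
  eps <- 1e-10 * max(1, abs(obs))
  perm_pval(sum(null >= obs - eps), length(null))
}

# Random permutation of 1..n performed independently within groups, so each
# group's members are shuffled among that group's positions only.
perm_within_groups <- function(groups) {
  idx <- seq_along(groups)
  for (g in unique(groups)) {
    w <- which(groups == g)
    idx[w] <- w[sample.int(length(w))]
  }
  idx
}

# Smooth random surface via random Fourier features: a stationary Gaussian
# process with squared-exponential-like covariance, exact and cheap to
# evaluate at arbitrary coordinates. Returns f(x, y).
random_surface <- function(length_scale, amplitude, n_features = 48L) {
  if (amplitude == 0) return(function(x, y) rep(0, length(x)))
  w <- matrix(stats::rnorm(2L * n_features, sd = 1 / length_scale),
              ncol = 2L)
  phase <- stats::runif(n_features, 0, 2 * pi)
  coef <- stats::rnorm(n_features)
  scale <- amplitude * sqrt(2 / n_features)
  function(x, y) {
    proj <- cbind(x, y) %*% t(w)  # n x K
    drop(scale * (cos(sweep(proj, 2L, phase, "+")) %*% coef))
  }
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# Delete-one jackknife standard error from leave-one-out estimates.
jackknife_se <- function(loo) {
  loo <- loo[is.finite(loo)]
  L <- length(loo)
  if (L < 2) return(NA_real_)
  sqrt((L - 1) / L * sum((loo - mean(loo))^2))
}
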