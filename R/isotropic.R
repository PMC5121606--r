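# Pair bookkeeping -----------------------------------------------------------

# Index pairs (i < j) eligible under a comparison mode: both members of
# `label` (within) or members of strictly different cohorts (between).
eligible_pairs <- function(cohort, mode = c("within", "between"),
                           label = NULL) {
  mode <- match.arg(mode)
  n <- length(cohort)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ut[, 1L]; j <- ut[, 2L]
  keep <- if (mode == "within") {
    if (is.null(label)) stop("within mode needs a cohort label")
    cohort[i] == label & cohort[j] == label
  } else {
    cohort[i] != cohort[j]
  }
  cbind(i = i[keep], j = j[keep])
}

mode_string <- function(mode, label) {
  if (mode == "between") "between_cohorts" else paste0("within_", label)
}

#' Sp coefficient from a kinship-distance slope and first-class kinship
#'
#' `Sp = -b_F / (1 - F_1)`: the intensity of fine-scale spatial genetic
#' structure, where `b_F` is the regression slope of pairwise kinship on
#' ln(distance) and `F_1` the mean kinship in the first distance class.
#'
#' @param b_F slope of kinship on ln(distance).
#' @param F_1 mean kinship in the first distance class.
#' @return The Sp coefficient.
#' @export
sp_coefficient <- function(b_F, F_1) -b_F / (1 - F_1)

#' Kinship-distance distogram with a permutation envelope
#'
#' Mean pairwise kinship `F_D` per contiguous distance class, with a null
#' distribution per class obtained by shuffling the genotype-to-location
#' assignment within each cohort and recomputing the class means. P-values
#' are two-sided; the envelope is the 2.5/97.5 percentile band from the
#' same draws.
#'
#' @param k a [kinship_matrix()].
#' @param dist pairwise distance matrix (meters), index-aligned with `k`.
#' @param mode `"within"` or `"between"` (cohorts).
#' @param label cohort label for `mode = "within"`.
#' @param config an [analysis_config()].
#' @return A data.frame of class `distogram`: class bounds, `n_pairs`,
#'   `F_D`, `envelope_lo/hi`, `p_value`.
#' @export
distogram <- function(k, dist, mode = c("within", "between"), label = NULL,
                      config = analysis_config()) {
  mode <- match.arg(mode)
  pairs <- eligible_pairs(as.character(k$cohort), mode, label)
  if (nrow(pairs) == 0L) stop("no eligible pairs for this mode")
  w <- config$distance_class_width
  d <- dist[pairs]
  cls <- pmax(1L, ceiling(d / w))  # d = 0 goes into class 1
  n_cls <- max(cls)
  y <- k$values[pairs]
  class_mean <- function(yy) {
    keep <- !is.na(yy)
    s <- rowsum(yy[keep], cls[keep])
    n <- rowsum(rep(1, sum(keep)), cls[keep])
    out <- rep(NA_real_, n_cls)
    out[as.integer(rownames(s))] <- s / n
    out
  }
  obs <- class_mean(y)
  n_pairs <- tabulate(cls, nbins = n_cls)

  set.seed(stage_seed(config$rng_seed, "distogram"))
  groups <- as.character(k$cohort)
  np <- config$n_perm_distogram
  null <- matrix(NA_real_, np, n_cls)
  for (b in seq_len(np)) {
    pm <- perm_within_groups(groups)
    null[b, ] <- class_mean(k$values[cbind(pm[pairs[, 1L]], pm[pairs[, 2L]])])
  }
  p <- env_lo <- env_hi <- rep(NA_real_, n_cls)
  for (ci in seq_len(n_cls)) {
    if (is.na(obs[ci])) next
    nb <- null[, ci][!is.na(null[, ci])]
    if (!length(nb)) next
    p[ci] <- perm_p_two_sided(nb, obs[ci])
    env_lo[ci] <- stats::quantile(nb, 0.025, names = FALSE)
    env_hi[ci] <- stats::quantile(nb, 0.975, names = FALSE)
  }
  out <- data.frame(class_lo = (seq_len(n_cls) - 1L) * w,
                    class_hi = seq_len(n_cls) * w,
                    n_pairs = n_pairs, F_D = obs,
                    envelope_lo = env_lo, envelope_hi = env_hi,
                    p_value = p)
  attr(out, "mode") <- mode_string(mode, label)
  attr(out, "n_perm") <- np
  class(out) <- c("distogram", "data.frame")
  out
}

# Core Sp machinery shared by the isotropic and sector-restricted paths.
# `pairs` is the eligible (i, j) index matrix; permutations shuffle
# genotype-to-location assignment within cohorts over the same pair set.
sp_core <- function(k, dist, pairs, config, density = NULL,
                    mode_label = "within", n_perm = NULL) {
  w <- config$distance_class_width
  d <- dist[pairs]
  y <- k$values[pairs]
  ok <- !is.na(y)
  pairs <- pairs[ok, , drop = FALSE]; d <- d[ok]; y <- y[ok]
  first_idx <- which(d < w)                # first class includes d = 0
  reg_idx_all <- which(d > 0)              # log regression excludes d = 0
  if (length(unique(d[reg_idx_all])) < 2L)
    stop("need >= 2 distinct pair distances for the kinship-distance slope")

  slope <- function(yy, idx) {
    x <- log(d[idx]); xc <- x - mean(x)
    sxx <- sum(xc^2)
    if (sxx == 0) return(NA_real_)
    sum(xc * yy[idx]) / sxx
  }
  estimate <- function(yy, idx) {
    b <- slope(yy, idx)
    f1 <- if (length(first_idx)) mean(yy[first_idx]) else NA_real_
    c(b_F = b, F_1 = f1, Sp = sp_coefficient(b, f1))
  }

  # iterative distance-range restriction (needs an effective density)
  reg_idx <- reg_idx_all
  range_used <- c(0, max(d))
  converged <- NA
  if (!is.null(density)) {
    est <- estimate(y, reg_idx)
    sigma_prev <- Inf; converged <- FALSE
    for (it in seq_len(20L)) {
      nb <- (1 - est[["F_1"]]) / est[["Sp"]]
      if (!is.finite(nb) || nb <= 0) break
      sigma <- sqrt(nb / (4 * pi * density))
      cand <- which(d > sigma & d < 20 * sigma)
      if (length(unique(d[cand])) < 2L) break
      reg_idx <- cand
      range_used <- c(sigma, min(20 * sigma, max(d)))
      est <- estimate(y, reg_idx)
      if (is.finite(sigma_prev) &&
          abs(sigma - sigma_prev) / sigma_prev < 0.01) { converged <- TRUE; break }
      sigma_prev <- sigma
    }
    if (!converged) { reg_idx <- reg_idx_all; range_used <- c(0, max(d)) }
  }

  est <- estimate(y, reg_idx)

  # jackknife over loci
  L <- length(k$den)
  se <- c(b_F = NA_real_, F_1 = NA_real_, Sp = NA_real_)
  loo <- NULL
  if (L >= 2L) {
    loo <- t(vapply(seq_len(L), function(l) {
      estimate(kinship_drop_locus(k, l)[pairs], reg_idx)
    }, c(b_F = 0, F_1 = 0, Sp = 0)))
    se <- apply(loo, 2L, jackknife_se)
  }

  # permutation test of Sp (two-sided), within-cohort shuffles
  np <- n_perm %||% config$n_perm_distogram
  set.seed(stage_seed(config$rng_seed, paste0("sp-", mode_label)))
  groups <- as.character(k$cohort)
  null_sp <- vapply(seq_len(np), function(b) {
    pm <- perm_within_groups(groups)
    yy <- k$values[cbind(pm[pairs[, 1L]], pm[pairs[, 2L]])]
    estimate(yy, reg_idx)[["Sp"]]
  }, 0)
  p_sp <- perm_p_two_sided(null_sp, est[["Sp"]])

  structure(list(b_F = est[["b_F"]], F_1 = est[["F_1"]], Sp = est[["Sp"]],
                 se_bF = se[["b_F"]], se_F1 = se[["F_1"]], se_Sp = se[["Sp"]],
                 p_Sp = p_sp,
                 jackknife = loo,
                 n_loci = L,
                 n_pairs = nrow(pairs),
                 n_pairs_regression = length(reg_idx),
                 distance_range_used = range_used,
                 range_restricted = !is.null(density) && isTRUE(converged),
                 mode = mode_label, n_perm = np),
            class = "sp_result")
}

#' @export
print.sp_result <- function(x, ...) {
  cat(sprintf("sp_result [%s]: b_F = %.4f (SE %.4f), F_1 = %.4f (SE %.4f)\n",
              x$mode, x$b_F, x$se_bF, x$F_1, x$se_F1))
  cat(sprintf("  Sp = %.4f (SE %.4f), permutation p = %.4g (%d perms, %d pairs)\n",
              x$Sp, x$se_Sp, x$p_Sp, x$n_perm, x$n_pairs))
  invisible(x)
}

#' Sp statistic of fine-scale SGS intensity
#'
#' Regresses pairwise kinship on ln(distance) to obtain `b_F`, takes `F_1`
#' as the mean kinship in the first distance class, and reports
#' `Sp = -b_F / (1 - F_1)` with jackknife-over-loci standard errors and a
#' permutation p-value (genotype-to-location shuffles within cohorts).
#' Co-located pairs (d = 0) are excluded from the log-distance regression
#' but counted in the first distance class. When an effective density is
#' supplied, the regression range is restricted iteratively to
#' `sigma < d < 20 sigma` with `sigma = sqrt(Nb / (4 pi D))`,
#' `Nb = (1 - F_1)/Sp`, until `sigma` changes by < 1% (at most 20
#' iterations); non-convergence falls back to the full range, flagged in
#' `range_restricted`.
#'
#' @inheritParams distogram
#' @param density optional effective population density (individuals per
#'   square meter) for the iterative range restriction.
#' @param n_perm override for the number of Sp permutations (defaults to
#'   `config$n_perm_distogram`).
#' @return An object of class `sp_result`.
#' @export
sp_statistic <- function(k, dist, mode = c("within", "between"), label = NULL,
                         config = analysis_config(), density = NULL,
                         n_perm = NULL) {
  mode <- match.arg(mode)
  pairs <- eligible_pairs(as.character(k$cohort), mode, label)
  if (nrow(pairs) < 2L) stop("need >= 2 eligible pairs")
  sp_core(k, dist, pairs, config, density,
          mode_label = mode_string(mode, label), n_perm = n_perm)
}

#' Compare SGS intensity between two analyses by t-test
#'
#' For each of `b_F`, `F_1` and `Sp`:
#' `t = (a - b) / sqrt(se_a^2 + se_b^2)`, two-sided p on Student's t with
#' `n_loci - 1` degrees of freedom, using the jackknife-over-loci standard
#' errors carried by the two [sp_statistic()] results.
#'
#' @param a,b `sp_result` objects with jackknife SEs.
#' @param n_loci number of loci (df = `n_loci - 1`).
#' @return A data.frame with one row per parameter: estimates, `t`, `p`.
#' @export
compare_cohorts <- function(a, b, n_loci) {
  params <- c("b_F", "F_1", "Sp")
  ses <- c(b_F = "se_bF", F_1 = "se_F1", Sp = "se_Sp")
  out <- lapply(params, function(p) {
    se_a <- a[[ses[[p]]]]; se_b <- b[[ses[[p]]]]
    if (is.na(se_a) || is.na(se_b)) stop("missing jackknife SE for ", p)
    delta <- a[[p]] - b[[p]]
    pooled <- sqrt(se_a^2 + se_b^2)
    tval <- if (pooled == 0) { if (delta == 0) 0 else Inf } else delta / pooled
    data.frame(parameter = p, estimate_a = a[[p]], estimate_b = b[[p]],
               t = tval,
               p_value = 2 * stats::pt(-abs(tval), df = n_loci - 1L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
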