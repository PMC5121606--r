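#' Bearing-weighted log-distance transform
#'
#' For a fixed compass direction `theta` (degrees clockwise from the +Y
#' axis), `T_ij(theta) = ln(d_ij) * cos^2(alpha_ij - theta)`, where
#' `alpha_ij` is the pairwise bearing. The transform is 180-degree periodic
#' in `theta`. Zero-distance pairs (undefined bearing/log) yield `NA` and
#' are excluded downstream.
#'
#' @param dist pairwise distance matrix (meters).
#' @param bearing pairwise bearing matrix (degrees in `[0, 180)`).
#' @param theta direction in degrees.
#' @return The transformed matrix.
#' @export
bearing_transform <- function(dist, bearing, theta) {
  T <- log(dist) * cos((bearing - theta) * pi / 180)^2
  T[dist == 0] <- NA_real_
  T
}

# Angular distance on the 180-degree (undirected bearing) circle.
half_circle_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Rosenberg bearing correlogram
#'
#' Profiles the Mantel (Pearson) correlation between pairwise kinship and
#' the bearing-weighted log-distance transform over `n_bearing_angles`
#' equidistant directions in `[0, 180)`. Significance per angle comes from
#' simultaneously permuting rows/columns of the kinship matrix; the same
#' permutation draws are reused across angles so the whole p-value profile
#' is a deterministic function of data and seed, and angles are mutually
#' comparable. `theta_s` (minimum r) marks the direction of strongest SGS,
#' `theta_w` (maximum r) the weakest. With `exact = TRUE` (n <= 7) the
#' permutation distribution is enumerated completely.
#'
#' @param k a [kinship_matrix()] (typically restricted to one cohort).
#' @param dist,bearing pairwise geometry matrices aligned with `k`.
#' @param config an [analysis_config()].
#' @param exact enumerate all `n!` permutations instead of sampling.
#' @return A list of class `bearing_correlogram`: data.frame `profile`
#'   (`angle`, `r`, `p_value`), `theta_s`, `theta_w`, `r_s`, `r_w`.
#' @export
bearing_correlogram <- function(k, dist, bearing, config = analysis_config(),
                                exact = FALSE) {
  n <- nrow(k$values)
  if (n < 4L) stop("need >= 4 individuals")
  ut <- which(upper.tri(dist), arr.ind = TRUE)
  d <- dist[ut]; al <- bearing[ut]
  keep <- d > 0 & !is.na(k$values[ut])
  ut <- ut[keep, , drop = FALSE]; d <- d[keep]; al <- al[keep]
  y <- k$values[ut]
  if (stats::sd(y) == 0) stop("constant kinship matrix; correlation undefined")

  angles <- seq(0, 180, length.out = config$n_bearing_angles + 1L)[
    seq_len(config$n_bearing_angles)]
  logd <- log(d)
  # pairs x angles matrix of standardized transforms
  Tm <- sapply(angles, function(th) logd * cos((al - th) * pi / 180)^2)
  Ts <- scale(Tm)
  if (any(!is.finite(Ts))) stop("degenerate bearing transform")
  ys <- function(v) (v - mean(v)) / stats::sd(v)
  np_pairs <- length(d)
  r_of <- function(v) drop(crossprod(Ts, ys(v))) / (np_pairs - 1)
  r_obs <- r_of(y)

  if (exact) {
    if (n > 7L) stop("exact enumeration limited to n <= 7")
    perms <- all_permutations(n)
    null <- t(vapply(seq_len(nrow(perms)), function(b) {
      pm <- perms[b, ]
      r_of(k$values[cbind(pm[ut[, 1L]], pm[ut[, 2L]])])
    }, numeric(length(angles))))
    # the identity permutation is part of the enumerated null
    p <- vapply(seq_along(angles), function(ai) {
      min(1, 2 * min(mean(null[, ai] >= r_obs[ai]),
                     mean(null[, ai] <= r_obs[ai])))
    }, 0)
    n_used <- nrow(perms)
  } else {
    set.seed(stage_seed(config$rng_seed, "bearing-correlogram"))
    np <- config$n_perm_mantel
    null <- matrix(NA_real_, np, length(angles))
    for (b in seq_len(np)) {
      pm <- sample.int(n)
      null[b, ] <- r_of(k$values[cbind(pm[ut[, 1L]], pm[ut[, 2L]])])
    }
    p <- vapply(seq_along(angles), function(ai)
      perm_p_two_sided(null[, ai], r_obs[ai]), 0)
    n_used <- np
  }

  profile <- data.frame(angle = angles, r = r_obs, p_value = p)
  i_s <- which.min(r_obs); i_w <- which.max(r_obs)
  structure(list(profile = profile,
                 theta_s = angles[i_s], theta_w = angles[i_w],
                 r_s = r_obs[i_s], r_w = r_obs[i_w],
                 p_s = p[i_s], p_w = p[i_w],
                 n_perm = n_used, exact = exact),
            class = "bearing_correlogram")
}

#' @export
print.bearing_correlogram <- function(x, ...) {
  cat(sprintf("bearing_correlogram: %d angles, %d permutations%s\n",
              nrow(x$profile), x$n_perm, if (x$exact) " (exact)" else ""))
  cat(sprintf("  theta_s = %.1f deg (r = %.3f, p = %.3g); theta_w = %.1f deg (r = %.3f, p = %.3g)\n",
              x$theta_s, x$r_s, x$p_s, x$theta_w, x$r_w, x$p_w))
  invisible(x)
}

# All permutations of 1..n as a matrix (n! rows); for exact Mantel nulls.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Sector-restricted Sp statistic at a fixed direction
#'
#' Restricts pair comparisons to those whose bearing lies within
#' `sector_halfwidth` degrees of `theta` on the 180-degree circle (so a
#' 30-degree sector around 170 degrees includes bearings near 5 degrees),
#' then computes the Sp statistic with the same first-class, jackknife and
#' permutation machinery as [sp_statistic()], permutations being evaluated
#' over the same restricted pair set.
#'
#' @inheritParams sp_statistic
#' @param bearing pairwise bearing matrix (degrees).
#' @param theta sector direction in degrees from the +Y axis.
#' @return An object of class `sp_result`.
#' @export
sector_sp <- function(k, dist, bearing, theta,
                      mode = c("within", "between"), label = NULL,
                      config = analysis_config(), density = NULL,
                      n_perm = NULL) {
  mode <- match.arg(mode)
  pairs <- eligible_pairs(as.character(k$cohort), mode, label)
  ad <- half_circle_dist(bearing[pairs], theta)
  in_sector <- !is.na(ad) & ad <= config$sector_halfwidth
  # co-located pairs have NA bearing; keep them for the F_1 class
  in_sector[is.na(ad)] <- TRUE
  pairs <- pairs[in_sector, , drop = FALSE]
  if (nrow(pairs) < 2L)
    stop(sprintf("fewer than 2 pairs in the sector around %.1f degrees", theta))
  sp_core(k, dist, pairs, config, density,
          mode_label = sprintf("%s_sector_%.1f", mode_string(mode, label), theta),
          n_perm = n_perm)
}
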