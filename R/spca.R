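#' Inverse-distance connection network
#'
#' Spatial weights `W_ij = 1 / d_ij` (zero diagonal), treating every pair
#' of plants as neighbours while discounting by distance. Co-located pairs
#' get the weight of half the smallest nonzero distance, keeping weights
#' finite. With `style = "row"` each row is standardized to sum 1 (the
#' convention for the lagged SAR models); `style = "raw"` keeps plain
#' reciprocal distances (the sPCA convention).
#'
#' @param frame a [spatial_frame()].
#' @param style `"raw"` or `"row"`.
#' @param truncate optional distance (meters) beyond which weights are set
#'   to zero (default: none, every pair connected).
#' @param k optional number of nearest neighbours; the adjacency is
#'   symmetrized (a pair is connected if either is among the other's `k`
#'   nearest). A local graph identifies the SAR lag coefficient much better
#'   than the fully dense network.
#' @return A list of class `connection_network` with `W`, `style`, `ids`.
#' @export
build_network <- function(frame, style = c("raw", "row"), truncate = NULL,
                          k = NULL) {
  style <- match.arg(style)
  geom <- pairwise_geometry(frame)
  d <- geom$dist
  off <- d[upper.tri(d)]
  eps <- if (any(off > 0)) min(off[off > 0]) / 2 else 1
  d[d == 0] <- eps
  W <- 1 / d
  diag(W) <- 0
  if (!is.null(truncate)) W[d > truncate] <- 0
  if (!is.null(k)) {
    n <- nrow(W)
    keep <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      nb <- order(d[i, ])
      nb <- setdiff(nb, i)[seq_len(min(k, n - 1L))]
      keep[i, nb] <- TRUE
    }
    keep <- keep | t(keep)
    W[!keep] <- 0
  }
  if (style == "row") {
    rs <- rowSums(W)
    if (any(rs == 0)) stop("isolated individual in connection network")
    W <- W / rs
  }
  structure(list(W = W, style = style, ids = frame$ids),
            class = "connection_network")
}

#' Moran's I spatial autocorrelation
#'
#' `I = (n / S0) * (z' W z) / (z' z)` with `z` the mean-centered variable
#' and `S0` the sum of all weights. Invariant to a global rescaling of `W`.
#'
#' @param z numeric vector.
#' @param W spatial weights matrix (zero diagonal).
#' @return Moran's I.
#' @export
moran_i <- function(z, W) {
  z <- z - mean(z)
  n <- length(z)
  s0 <- sum(W)
  (n / s0) * drop(z %*% W %*% z) / sum(z^2)
}

# Centered allele-frequency matrix for one cohort: one column per allele,
# values 0 / 0.5 / 1, missing imputed by column mean (sPCA only; the kinship
# module never imputes), monomorphic columns dropped, columns centered.
spca_design_matrix <- function(g, cohort = NULL) {
  keep <- if (is.null(cohort)) rep(TRUE, n_ind(g)) else g$cohort == cohort
  gg <- subset_genotypes(g, keep)
  dm <- dosage_matrix(gg)
  X <- dm$X
  for (j in seq_len(ncol(X))) {
    mis <- is.na(X[, j])
    if (all(mis)) stop("allele column with no scored individuals")
    if (any(mis)) X[mis, j] <- mean(X[!mis, j])
  }
  poly <- apply(X, 2L, function(v) stats::sd(v) > 0)
  X <- X[, poly, drop = FALSE]
  scale(X, center = TRUE, scale = FALSE)
}

#' Spatial principal component analysis of allele frequencies
#'
#' Decomposes `(1/(2n)) X' (W + W') X` where `X` is the centered
#' allele-frequency matrix of a cohort and `W` the connection network
#' (internally rescaled so that its weights sum to `n`, which leaves
#' Moran's I unchanged and makes each eigenvalue exactly the product of the
#' variance and Moran's I of its score). Large positive eigenvalues mark
#' global structures (clines, patches of positive autocorrelation); large
#' negative eigenvalues mark local structures (neighbour contrasts).
#'
#' @param g a [genotype_table()].
#' @param net a [build_network()] network aligned with the cohort's
#'   individuals.
#' @param cohort optional cohort label; default uses all individuals.
#' @return A list of class `spca_result`: `eigenvalues` (descending),
#'   `scores`, `loadings`, `var` and `moran` per component.
#' @export
spca_fit <- function(g, net, cohort = NULL) {
  X <- spca_design_matrix(g, cohort)
  n <- nrow(X)
  if (n < 3L) stop("need >= 3 individuals")
  W <- net$W
  if (nrow(W) != n) stop("network size does not match cohort size")
  Ws <- (W + t(W)) / 2
  s0 <- sum(Ws)
  if (s0 > 0) Ws <- Ws * (n / s0)
  C <- crossprod(X, Ws %*% X) / n   # == (1/(2n)) X'(W + W')X after scaling
  C <- (C + t(C)) / 2
  eig <- eigen(C, symmetric = TRUE)
  ord <- order(eig$values, decreasing = TRUE)
  lambda <- eig$values[ord]
  V <- eig$vectors[, ord, drop = FALSE]
  S <- X %*% V
  v_var <- colSums(S^2) / n
  mor <- apply(S, 2L, function(z) if (sum(z^2) > 0) moran_i(z, Ws) else NA_real_)
  colnames(S) <- colnames(V) <- paste0("PC", seq_len(ncol(S)))
  rownames(V) <- colnames(X)
  structure(list(eigenvalues = lambda, scores = S, loadings = V,
                 var = v_var, moran = mor, n = n,
                 trace = sum(diag(C)), cohort = cohort),
            class = "spca_result")
}

#' @export
print.spca_result <- function(x, ...) {
  cat(sprintf("spca_result: n = %d, %d components\n", x$n,
              length(x$eigenvalues)))
  k <- seq_len(min(5L, length(x$eigenvalues)))
  cat("  leading eigenvalues:",
      paste(sprintf("%.4f", x$eigenvalues[k]), collapse = ", "), "\n")
  invisible(x)
}

# Moran eigenvector basis of the symmetrized, doubly centered network, with
# the trivial constant direction removed; returns vectors and their Moran's I.
moran_eigenvectors <- function(W) {
  n <- nrow(W)
  Ws <- (W + t(W)) / 2
  H <- diag(n) - matrix(1 / n, n, n)
  E <- eigen(H %*% Ws %*% H, symmetric = TRUE)
  U <- E$vectors
  # drop the direction aligned with the constant vector
  aligned <- which.max(abs(colMeans(U)))
  U <- U[, -aligned, drop = FALSE]
  I <- apply(U, 2L, moran_i, W = Ws)
  list(U = U, I = I)
}

#' Permutation test for global or local spatial genetic structure
#'
#' Jombart-style test: project allele-frequency columns onto the Moran
#' eigenvector basis of the network, compute `t_u`, the mean squared
#' correlation between the allele columns and eigenvector `u`, order the
#' eigenvectors by decreasing (global) or increasing (local) Moran's I
#' keeping only those on the relevant side of the null expectation
#' `-1/(n-1)`, and take as statistic the maximum over a sliding window of
#' `smooth` consecutive `t` values of their mean. The null permutes the
#' individual rows of the genotype matrix.
#'
#' @inheritParams spca_fit
#' @param which `"global"` or `"local"`.
#' @param n_perm number of row permutations.
#' @param smooth sliding-window width (1 = unsmoothed maximum).
#' @return A list with `statistic` (max(t)), `p_value`, `which`, `t`.
#' @export
global_local_test <- function(g, net, cohort = NULL,
                              which = c("global", "local"),
                              n_perm = 999L, smooth = 3L) {
  which <- match.arg(which)
  X <- spca_design_matrix(g, cohort)
  n <- nrow(X)
  if (n < 4L) stop("need >= 4 individuals")
  me <- moran_eigenvectors(net$W)
  i0 <- -1 / (n - 1)
  side <- if (which == "global") me$I > i0 else me$I < i0
  if (!any(side)) stop("no Moran eigenvectors on the requested side")
  ord <- order(me$I, decreasing = (which == "global"))
  ord <- ord[side[ord]]
  U <- me$U[, ord, drop = FALSE]

  stat_of <- function(Xm) {
    R <- suppressWarnings(stats::cor(Xm, U))   # columns x eigenvectors
    t_u <- colMeans(R^2, na.rm = TRUE)
    k <- length(t_u)
    w <- min(smooth, k)
    sm <- vapply(seq_len(k - w + 1L), function(s) mean(t_u[s:(s + w - 1L)]), 0)
    list(stat = max(sm), t = t_u)
  }
  obs <- stat_of(X)
  null <- vapply(seq_len(n_perm), function(b)
    stat_of(X[sample.int(n), , drop = FALSE])$stat, 0)
  list(statistic = obs$stat,
       p_value = perm_pval(sum(null >= obs$stat), n_perm),
       which = which, t = obs$t, n_perm = n_perm)
}
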