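#' Pairwise Loiselle/Nason kinship coefficients
#'
#' Computes the kinship (coancestry) coefficient of Loiselle et al. for all
#' pairs of individuals, referenced to sample allele frequencies. Per locus
#' `l`,
#' \deqn{F_{ij,l} = \frac{\sum_a (p_{ila} - p_{la})(p_{jla} - p_{la}) +
#'   p_{la}(1-p_{la})/(n_l - 1)}{\sum_a p_{la}(1 - p_{la})}}
#' where `p_ila` is the frequency of allele `a` within individual `i`
#' (0, 1/2 or 1 for diploids; 0 or 1 for the haploid plastid marker),
#' `p_la` the reference frequency, and `n_l` the number of gene copies
#' scored at the locus in the reference sample (twice the scored
#' individuals for diploid loci). Counting gene copies makes the pairwise
#' mean of the estimator unbiased around zero for unstructured samples at
#' either ploidy. The multilocus coefficient
#' is the ratio of summed numerators to summed denominators over the loci
#' scored in both individuals (pairwise deletion of missing calls).
#'
#' @param g a [genotype_table()].
#' @param marker `"ssr"` (diploid nuclear loci) or `"plastid"` (the haploid
#'   haplotype treated as a single-locus haploid marker).
#' @param freq_scope `"pooled"` (reference frequencies from the whole
#'   sample; all pairs defined) or `"per_cohort"` (frequencies computed
#'   within each cohort; only within-cohort pairs defined).
#' @return A list of class `kinship_matrix` with `values` (n x n multilocus
#'   matrix, diagonal `NA`), `per_locus` (n x n x L array of per-locus
#'   ratios), `num`/`den` (per-locus numerator array and denominator
#'   vector, used for jackknifing), `freqs`, `n_scored`, `ploidy`, `ids`
#'   and `cohort`.
#' @export
kinship_matrix <- function(g, marker = c("ssr", "plastid"),
                           freq_scope = c("pooled", "per_cohort")) {
  marker <- match.arg(marker)
  freq_scope <- match.arg(freq_scope)
  if (n_ind(g) < 3L) stop("need at least 3 individuals")
  dm <- if (marker == "ssr") dosage_matrix(g) else haplotype_dosage(g)
  copies_per_ind <- if (marker == "ssr") 2L else 1L
  n <- n_ind(g)
  loci <- unique(dm$locus)
  L <- length(loci)
  num <- array(NA_real_, dim = c(n, n, L))
  den <- rep(NA_real_, L)
  freqs <- vector("list", L)
  n_scored <- integer(L)

  groups <- if (freq_scope == "pooled") rep("all", n) else as.character(g$cohort)

  for (li in seq_len(L)) {
    cols <- which(dm$locus == loci[li])
    P <- dm$X[, cols, drop = FALSE]
    scored <- !is.na(P[, 1L])
    Nl <- matrix(NA_real_, n, n)
    den_parts <- c()
    for (grp in unique(groups)) {
      in_g <- groups == grp
      sg <- scored & in_g
      nl <- sum(sg)
      if (nl < 2L) next
      p <- colMeans(P[sg, , drop = FALSE])
      dsum <- sum(p * (1 - p))
      if (dsum == 0) next  # monomorphic within this reference sample
      Pc <- sweep(P, 2L, p)
      Pc[!sg, ] <- 0
      M <- tcrossprod(Pc) + dsum / (copies_per_ind * nl - 1)
      M[!sg, ] <- NA_real_; M[, !sg] <- NA_real_
      if (freq_scope == "per_cohort") { M[!in_g, ] <- NA_real_; M[, !in_g] <- NA_real_ }
      keep <- !is.na(M)
      Nl[keep] <- M[keep]
      den_parts <- c(den_parts, dsum)
      if (grp == unique(groups)[1L]) {
        freqs[[li]] <- p
        n_scored[li] <- nl
      }
    }
    if (length(den_parts) == 0L) {
      warning("locus ", li, " monomorphic in reference sample; skipped")
      next
    }
    # with per-cohort scope the denominators differ by cohort; encode by
    # normalizing numerators to a common unit denominator in that case
    if (freq_scope == "per_cohort" && length(unique(groups)) > 1L) {
      # divide each cohort block by its own denominator; den becomes 1
      pos <- 0L
      for (grp in unique(groups)) {
        in_g <- groups == grp
        sg <- scored & in_g
        if (sum(sg) < 2L) next
        p <- colMeans(P[sg, , drop = FALSE])
        dsum <- sum(p * (1 - p))
        if (dsum == 0) next
        Nl[in_g, in_g] <- Nl[in_g, in_g] / dsum
      }
      den[li] <- 1
    } else {
      den[li] <- den_parts[1L]
    }
    num[, , li] <- Nl
  }
  ok <- !is.na(den)
  if (!any(ok)) stop("no polymorphic locus available for kinship")
  num <- num[, , ok, drop = FALSE]
  den <- den[ok]
  L <- sum(ok)

  valid <- !is.na(num)
  num0 <- num; num0[!valid] <- 0
  sum_n <- apply(num0, c(1L, 2L), sum)
  sum_d <- matrix(0, n, n)
  for (li in seq_len(L)) sum_d <- sum_d + valid[, , li] * den[li]
  values <- ifelse(sum_d > 0, sum_n / sum_d, NA_real_)
  diag(values) <- NA_real_
  per_locus <- num
  for (li in seq_len(L)) per_locus[, , li] <- num[, , li] / den[li]
  dimnames(values) <- list(g$ids, g$ids)

  structure(list(values = values, per_locus = per_locus,
                 num = num, den = den,
                 freqs = freqs[ok], n_scored = n_scored[ok],
                 ploidy = if (marker == "ssr") "diploid" else "haploid",
                 marker = marker, freq_scope = freq_scope,
                 ids = g$ids, cohort = g$cohort),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d individuals, %d loci (%s, %s freqs)\n",
              nrow(x$values), length(x$den), x$ploidy, x$freq_scope))
  cat(sprintf("  mean pairwise F = %.4f\n",
              mean(x$values[upper.tri(x$values)], na.rm = TRUE)))
  invisible(x)
}

# Multilocus kinship recomputed with locus `drop` removed (ratio of sums),
# for jackknife-over-loci resampling. Returns the full n x n matrix.
kinship_drop_locus <- function(k, drop) {
  L <- length(k$den)
  if (L < 2L) stop("cannot jackknife a single-locus marker")
  keep <- setdiff(seq_len(L), drop)
  valid <- !is.na(k$num)
  num0 <- k$num; num0[!valid] <- 0
  sum_n <- apply(num0[, , keep, drop = FALSE], c(1L, 2L), sum)
  sum_d <- matrix(0, nrow(k$values), ncol(k$values))
  for (li in keep) sum_d <- sum_d + valid[, , li] * k$den[li]
  v <- ifelse(sum_d > 0, sum_n / sum_d, NA_real_)
  diag(v) <- NA_real_
  v
}

#' Write a kinship matrix as square TSV
#' @param k a [kinship_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(k, path) {
  df <- data.frame(id = rownames(k$values), k$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
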