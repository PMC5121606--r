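#' Per-locus, per-cohort diversity summaries
#'
#' For each locus and cohort: allelic richness (count of distinct alleles),
#' percentage of missing calls, observed heterozygosity `H_O`, Nei's
#' unbiased expected heterozygosity
#' `H_E = 2n/(2n-1) * (1 - sum(p_a^2))`, and the inbreeding coefficient
#' `F_IS = 1 - H_O / H_E` (NA-flagged when `H_E = 0`).
#'
#' @param g a [genotype_table()].
#' @return A data.frame with one row per locus x cohort.
#' @export
locus_summaries <- function(g) {
  if (any(table(g$cohort) < 2L)) stop("need >= 2 individuals per cohort")
  out <- list()
  for (lab in levels(g$cohort)) {
    idx <- g$cohort == lab
    for (l in seq_along(g$loci)) {
      a1 <- g$calls[idx, l, 1L]; a2 <- g$calls[idx, l, 2L]
      scored <- !is.na(a1)
      nl <- sum(scored)
      pct_missing <- 100 * mean(!scored)
      if (nl == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          locus = g$loci[l], cohort = lab, n = 0L, allelic_richness = 0L,
          pct_missing = pct_missing, h_obs = NA_real_, h_exp = NA_real_,
          f_is = NA_real_, stringsAsFactors = FALSE)
        next
      }
      alleles <- c(a1[scored], a2[scored])
      p <- as.numeric(table(alleles)) / (2 * nl)
      h_obs <- mean(a1[scored] != a2[scored])
      h_exp <- (2 * nl) / (2 * nl - 1) * (1 - sum(p^2))
      f_is <- if (h_exp > 0) 1 - h_obs / h_exp else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        locus = g$loci[l], cohort = lab, n = nl,
        allelic_richness = length(p), pct_missing = pct_missing,
        h_obs = h_obs, h_exp = h_exp, f_is = f_is,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Inbreeding coefficient from observed and expected heterozygosity
#'
#' `F_IS = 1 - H_O / H_E`; positive values mark a heterozygote deficit.
#'
#' @param h_obs observed heterozygosity.
#' @param h_exp expected (unbiased) heterozygosity, > 0.
#' @return The inbreeding coefficient.
#' @export
inbreeding_coefficient <- function(h_obs, h_exp) 1 - h_obs / h_exp

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' The statistic is the chi-squared distance between observed genotype
#' counts and their Hardy-Weinberg expectations given the observed allele
#' frequencies. The null distribution is built by shuffling the `2n` allele
#' copies into random diploid genotypes `n_perm` times; the p-value follows
#' the `(1 + hits) / (1 + n_perm)` convention.
#'
#' @param g a [genotype_table()].
#' @param locus locus name.
#' @param cohort cohort label.
#' @param n_perm number of Monte-Carlo shuffles.
#' @return A list with `statistic` (chi-squared) and `p_value`.
#' @export
hwe_test <- function(g, locus, cohort, n_perm = 999L) {
  l <- match(locus, g$loci)
  if (is.na(l)) stop("unknown locus: ", locus)
  idx <- g$cohort == cohort
  a1 <- g$calls[idx, l, 1L]; a2 <- g$calls[idx, l, 2L]
  scored <- !is.na(a1)
  if (!any(scored)) stop("all individuals missing at locus ", locus)
  a1 <- a1[scored]; a2 <- a2[scored]
  nl <- length(a1)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2L) stop("locus ", locus, " monomorphic in cohort ", cohort)

  chisq_stat <- function(x1, x2) {
    i1 <- match(x1, alleles); i2 <- match(x2, alleles)
    lo <- pmin(i1, i2); hi <- pmax(i1, i2)
    obs <- table(factor(lo, levels = seq_along(alleles)),
                 factor(hi, levels = seq_along(alleles)))
    cnt <- tabulate(c(i1, i2), nbins = length(alleles))
    p <- cnt / (2 * nl)
    ex <- outer(p, p) * nl
    ex <- ex + t(ex)          # unordered heterozygote expectation 2*n*pa*pb
    diag(ex) <- nl * p^2
    ut <- upper.tri(ex, diag = TRUE)
    keep <- ex[ut] > 0
    sum((obs[ut][keep] - ex[ut][keep])^2 / ex[ut][keep])
  }

  obs_stat <- chisq_stat(a1, a2)
  copies <- c(a1, a2)
  null <- vapply(seq_len(n_perm), function(i) {
    s <- sample(copies)
    chisq_stat(s[seq_len(nl)], s[nl + seq_len(nl)])
  }, 0)
  list(statistic = obs_stat,
       p_value = perm_pval(sum(null >= obs_stat), n_perm))
}

# Weir & Cockerham (1984) theta variance components per locus.
# Returns c(a, b, c) summed over alleles, for exactly 2 cohorts.
wc_components <- function(a1, a2, pop) {
  scored <- !is.na(a1)
  a1 <- a1[scored]; a2 <- a2[scored]; pop <- pop[scored]
  pops <- unique(pop)
  r <- length(pops)
  if (r < 2L) return(c(a = 0, b = 0, c = 0))
  alleles <- sort(unique(c(a1, a2)))
  n_i <- as.numeric(table(factor(pop, levels = pops)))
  if (any(n_i < 1)) return(c(a = 0, b = 0, c = 0))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  A <- 0; B <- 0; C <- 0
  for (al in alleles) {
    p_i <- vapply(pops, function(g)
      (sum(a1[pop == g] == al) + sum(a2[pop == g] == al)) / (2 * sum(pop == g)), 0)
    h_i <- vapply(pops, function(g)
      mean((a1[pop == g] == al) != (a2[pop == g] == al)), 0)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a_c <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b_c <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    c_c <- hbar / 2
    A <- A + a_c; B <- B + b_c; C <- C + c_c
  }
  c(a = A, b = B, c = C)
}

#' Weir-Cockerham F_ST between two cohorts with a permutation test
#'
#' Computes theta per locus and multilocus (ratio of summed variance
#' components over loci) and tests `F_ST > 0` by permuting cohort labels
#' over individuals.
#'
#' @param g a [genotype_table()] with exactly two cohorts.
#' @param n_perm permutations of cohort labels.
#' @return A list with `fst` (multilocus theta), `fst_per_locus`, `p_value`
#'   (one-sided), and `n_perm`.
#' @export
fst_between_cohorts <- function(g, n_perm = 500L) {
  if (nlevels(g$cohort) != 2L) stop("exactly 2 cohorts required")
  if (any(table(g$cohort) < 2L)) stop("each cohort needs >= 2 individuals")
  pop <- as.character(g$cohort)
  L <- length(g$loci)

  theta_all <- function(pop_labels) {
    comps <- vapply(seq_len(L), function(l)
      wc_components(g$calls[, l, 1L], g$calls[, l, 2L], pop_labels),
      c(a = 0, b = 0, c = 0))
    tot <- rowSums(comps)
    denom <- sum(tot)
    per <- ifelse(colSums(comps) != 0, comps["a", ] / colSums(comps), NA_real_)
    list(multi = if (denom != 0) tot[["a"]] / denom else NA_real_, per = per)
  }

  obs <- theta_all(pop)
  null <- vapply(seq_len(n_perm), function(i) theta_all(sample(pop))$multi, 0)
  list(fst = obs$multi,
       fst_per_locus = stats::setNames(obs$per, g$loci),
       p_value = perm_pval(sum(null >= obs$multi, na.rm = TRUE), n_perm),
       n_perm = n_perm)
}

#' Pairwise chord distances between individual genotypes
#'
#' `D_ij = sqrt(2 (1 - (1/L_ij) sum_l sum_a sqrt(p_ila p_jla)))` over the
#' `L_ij` loci scored in both individuals, with `p_ila` the within-individual
#' allele frequency (0, 1/2, 1). Identical multilocus genotypes have
#' distance 0.
#'
#' @param g a [genotype_table()].
#' @return An n x n distance matrix (NA for pairs sharing no scored locus).
#' @export
chord_distances <- function(g) {
  dm <- dosage_matrix(g)
  n <- n_ind(g)
  loci <- unique(dm$locus)
  S <- matrix(0, n, n)       # sum over loci of sum_a sqrt(p_i p_j)
  shared <- matrix(0, n, n)  # number of shared scored loci
  for (l in loci) {
    cols <- which(dm$locus == l)
    P <- dm$X[, cols, drop = FALSE]
    scored <- !is.na(P[, 1L])
    R <- sqrt(P); R[!scored, ] <- 0
    S <- S + tcrossprod(R)
    shared <- shared + outer(scored, scored, "&")
  }
  D <- ifelse(shared > 0, sqrt(pmax(0, 2 * (1 - S / shared))), NA_real_)
  diag(D) <- 0
  dimnames(D) <- list(g$ids, g$ids)
  D
}

#' AMOVA between cohorts on individual chord distances
#'
#' Excoffier-style analysis of molecular variance: sums of squares are
#' computed from squared pairwise distances (`SS = sum d^2 / n` within each
#' grouping), partitioned among and within cohorts, with the among-cohort
#' variance component `sigma2_among = (MS_among - MS_within) / n0`. The
#' permutation null shuffles cohort labels over individuals.
#'
#' @param g a [genotype_table()] with exactly two cohorts.
#' @param n_perm number of label permutations.
#' @return A list with `sigma2_among` (clamped at 0), `sigma2_among_raw`,
#'   `sigma2_within`, `phi_st`, `p_value` and the SS table.
#' @export
amova_chord <- function(g, n_perm = 999L) {
  if (nlevels(g$cohort) != 2L) stop("exactly 2 cohorts required")
  D <- chord_distances(g)
  if (anyNA(D)) {
    bad <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    warning(nrow(bad), " pair(s) share no scored locus; excluded")
    D[is.na(D)] <- 0
  }
  D2 <- D^2
  pop <- as.character(g$cohort)
  components <- function(labels) {
    N <- length(labels)
    groups <- unique(labels)
    ss_total <- sum(D2[upper.tri(D2)]) / N
    ss_within <- 0
    for (grp in groups) {
      w <- labels == grp
      ss_within <- ss_within + sum(D2[w, w][upper.tri(D2[w, w])]) / sum(w)
    }
    ss_among <- ss_total - ss_within
    g_n <- as.numeric(table(factor(labels, levels = groups)))
    df_among <- length(groups) - 1L
    df_within <- N - length(groups)
    n0 <- (N - sum(g_n^2) / N) / df_among
    ms_among <- ss_among / df_among
    ms_within <- ss_within / df_within
    s2w <- ms_within
    s2a <- (ms_among - ms_within) / n0
    c(s2a = s2a, s2w = s2w, ss_among = ss_among, ss_within = ss_within)
  }
  obs <- components(pop)
  null <- vapply(seq_len(n_perm), function(i) components(sample(pop))["s2a"], 0)
  phi <- obs[["s2a"]] / (obs[["s2a"]] + obs[["s2w"]])
  list(sigma2_among = max(obs[["s2a"]], 0),
       sigma2_among_raw = obs[["s2a"]],
       sigma2_within = obs[["s2w"]],
       phi_st = phi,
       p_value = perm_pval(sum(null >= obs[["s2a"]]), n_perm),
       ss = c(among = obs[["ss_among"]], within = obs[["ss_within"]]),
       n_perm = n_perm)
}
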