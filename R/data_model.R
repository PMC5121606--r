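#' Georeferenced multilocus genotype table
#'
#' The central container of the package: diploid codominant allele calls
#' (e.g. nuclear microsatellites) for a set of individuals belonging to one
#' or more cohorts, with an optional haploid (plastid) haplotype per
#' individual. Allele codes are opaque non-negative integers; no repeat-motif
#' semantics are attached.
#'
#' @param ids character vector of unique individual identifiers.
#' @param cohort vector of cohort labels, one per individual.
#' @param calls integer array `n x L x 2` of allele codes; `NA` marks a
#'   missing call. A call missing one of its two slots is normalized to a
#'   fully missing call.
#' @param loci character vector of `L` locus names.
#' @param haplotype optional vector (length `n`) of haploid haplotype codes,
#'   `NA` allowed.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(ids, cohort, calls, loci, haplotype = NULL) {
  ids <- as.character(ids)
  n <- length(ids)
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (length(cohort) != n) stop("cohort labels must match individuals")
  if (length(dim(calls)) != 3L || dim(calls)[3] != 2L)
    stop("calls must be an n x L x 2 array")
  if (dim(calls)[1] != n) stop("calls rows must match individuals")
  if (dim(calls)[2] != length(loci)) stop("calls columns must match loci")
  storage.mode(calls) <- "integer"
  if (any(calls < 0, na.rm = TRUE)) stop("allele codes must be non-negative")
  # half-missing calls become fully missing
  half <- is.na(calls[, , 1L, drop = FALSE]) != is.na(calls[, , 2L, drop = FALSE])
  if (any(half)) {
    calls[, , 1L][half[, , 1L]] <- NA_integer_
    calls[, , 2L][half[, , 1L]] <- NA_integer_
  }
  dimnames(calls) <- list(ids, loci, c("a1", "a2"))
  if (!is.null(haplotype)) {
    if (length(haplotype) != n) stop("haplotype must have one entry per individual")
    haplotype <- as.character(haplotype)
  }
  structure(list(
    ids = ids,
    cohort = factor(as.character(cohort)),
    loci = as.character(loci),
    calls = calls,
    haplotype = haplotype
  ), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals, %d loci, cohorts: %s\n",
              length(x$ids), length(x$loci),
              paste(levels(x$cohort), collapse = ", ")))
  miss <- mean(is.na(x$calls[, , 1L]))
  cat(sprintf("  missing calls: %.1f%%; haplotype: %s\n", 100 * miss,
              if (is.null(x$haplotype)) "absent" else "present"))
  invisible(x)
}

n_ind <- function(g) length(g$ids)

subset_genotypes <- function(g, keep) {
  keep <- if (is.logical(keep)) which(keep) else keep
  genotype_table(g$ids[keep], as.character(g$cohort)[keep],
                 g$calls[keep, , , drop = FALSE], g$loci,
                 haplotype = g$haplotype[keep])
}

#' Read genotypes from GENEPOP or tidy CSV
#'
#' GENEPOP dialect: title line, locus names (one per line or comma separated),
#' `pop` blocks with `id , a1a2 a1a2 ...` rows using 2- or 3-digit allele
#' codes; `00`/`000` codes become missing. Each `pop` block becomes one
#' cohort. The CSV dialect expects columns `individual_id`, `cohort`,
#' optionally `haplotype`, and one `a1/a2` column per locus (`NA` or empty =
#' missing).
#'
#' @param path file path.
#' @param format `"genepop"` or `"csv"`.
#' @param cohort_labels optional character vector renaming the GENEPOP pop
#'   blocks (defaults to `pop_1`, `pop_2`, ...).
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("genepop", "csv"),
                           cohort_labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "genepop") read_genepop(path, cohort_labels)
  else read_genotypes_csv(path)
}

read_genepop <- function(path, cohort_labels = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 4L) stop("GENEPOP file too short")
  body <- lines[-1L]  # drop title
  pop_at <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_at) == 0L) stop("no 'pop' line found")
  loc_lines <- body[seq_len(pop_at[1L] - 1L)]
  loci <- unlist(strsplit(loc_lines, ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0L) stop("no locus names found")

  ids <- character(); cohort <- character(); rows <- list()
  width <- NA_integer_
  pop_bounds <- c(pop_at, length(body) + 1L)
  for (b in seq_along(pop_at)) {
    lab <- if (!is.null(cohort_labels)) cohort_labels[b] else sprintf("pop_%d", b)
    from <- pop_bounds[b] + 1L; to <- pop_bounds[b + 1L] - 1L
    if (to < from) stop("empty pop block ", b)
    for (ln in from:to) {
      line <- body[ln]
      parts <- strsplit(line, ",")[[1L]]
      if (length(parts) != 2L)
        stop(sprintf("malformed GENEPOP row at line %d: missing ','", ln + 1L))
      id <- trimws(parts[1L])
      toks <- strsplit(trimws(parts[2L]), "\\s+")[[1L]]
      toks <- toks[nzchar(toks)]
      if (length(toks) != length(loci))
        stop(sprintf("malformed GENEPOP row at line %d: %d genotypes for %d loci",
                     ln + 1L, length(toks), length(loci)))
      w <- unique(nchar(toks))
      if (length(w) != 1L || !(w %in% c(4L, 6L)))
        stop(sprintf("inconsistent allele-code width at line %d", ln + 1L))
      w <- w / 2L
      if (is.na(width)) width <- w
      if (w != width)
        stop(sprintf("inconsistent allele-code width at line %d", ln + 1L))
      a1 <- as.integer(substr(toks, 1L, width))
      a2 <- as.integer(substr(toks, width + 1L, 2L * width))
      if (anyNA(a1) || anyNA(a2))
        stop(sprintf("non-numeric allele code at line %d", ln + 1L))
      a1[a1 == 0L] <- NA_integer_
      a2[a2 == 0L] <- NA_integer_
      ids <- c(ids, id); cohort <- c(cohort, lab)
      rows[[length(rows) + 1L]] <- cbind(a1, a2)
    }
  }
  calls <- array(NA_integer_, dim = c(length(ids), length(loci), 2L))
  for (i in seq_along(rows)) calls[i, , ] <- rows[[i]]
  genotype_table(ids, cohort, calls, loci)
}

read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  req <- c("individual_id", "cohort")
  if (!all(req %in% names(df)))
    stop("genotype CSV needs columns: ", paste(req, collapse = ", "))
  hap <- if ("haplotype" %in% names(df)) df$haplotype else NULL
  if (!is.null(hap)) hap[hap %in% c("", "NA")] <- NA_character_
  loci <- setdiff(names(df), c("individual_id", "cohort", "haplotype"))
  if (length(loci) == 0L) stop("no locus columns in ", path)
  n <- nrow(df)
  calls <- array(NA_integer_, dim = c(n, length(loci), 2L))
  for (l in seq_along(loci)) {
    v <- df[[loci[l]]]
    miss <- is.na(v) | v %in% c("", "NA")
    ok <- which(!miss)
    if (length(ok)) {
      sp <- strsplit(v[ok], "/", fixed = TRUE)
      bad <- lengths(sp) != 2L
      if (any(bad))
        stop(sprintf("malformed genotype '%s' at row %d, locus %s",
                     v[ok][bad][1L], ok[bad][1L], loci[l]))
      m <- matrix(as.integer(unlist(sp)), ncol = 2L, byrow = TRUE)
      calls[ok, l, 1L] <- m[, 1L]
      calls[ok, l, 2L] <- m[, 2L]
    }
  }
  genotype_table(df$individual_id, df$cohort, calls, loci, haplotype = hap)
}

#' Write genotypes to GENEPOP or tidy CSV
#'
#' @param g a [genotype_table()].
#' @param path output file path.
#' @param format `"genepop"` or `"csv"`.
#' @param title title line for GENEPOP output.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("genepop", "csv"),
                            title = "finesgs genotypes") {
  format <- match.arg(format)
  if (format == "csv") {
    gt <- matrix(NA_character_, n_ind(g), length(g$loci))
    ok <- !is.na(g$calls[, , 1L, drop = FALSE][, , 1L])
    gt[ok] <- paste0(g$calls[, , 1L][ok], "/", g$calls[, , 2L][ok])
    df <- data.frame(individual_id = g$ids,
                     cohort = as.character(g$cohort),
                     stringsAsFactors = FALSE)
    if (!is.null(g$haplotype)) df$haplotype <- g$haplotype
    df <- cbind(df, as.data.frame(gt, stringsAsFactors = FALSE))
    names(df)[(ncol(df) - length(g$loci) + 1L):ncol(df)] <- g$loci
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(title, con)
    writeLines(g$loci, con)
    for (lab in levels(g$cohort)) {
      writeLines("pop", con)
      for (i in which(g$cohort == lab)) {
        a <- g$calls[i, , 1L]; b <- g$calls[i, , 2L]
        a[is.na(a)] <- 0L; b[is.na(b)] <- 0L
        writeLines(sprintf("%s ,  %s", g$ids[i],
                           paste0(sprintf("%03d%03d", a, b), collapse = " ")),
                   con)
      }
    }
  }
  invisible(path)
}

#' Per-individual spatial coordinates on a rectangular plot
#'
#' @param ids character individual identifiers.
#' @param x,y coordinates in meters (plot origin at lower-left).
#' @param bounds numeric `c(xmin, xmax, ymin, ymax)`; defaults to the data
#'   range.
#' @return An object of class `spatial_frame`.
#' @export
spatial_frame <- function(ids, x, y, bounds = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  stopifnot(length(x) == length(ids), length(y) == length(ids))
  if (anyNA(x) || anyNA(y)) stop("coordinates must not be missing")
  if (is.null(bounds)) bounds <- c(range(x), range(y))
  if (any(x < bounds[1] | x > bounds[2] | y < bounds[3] | y > bounds[4]))
    stop("coordinates outside plot bounds")
  structure(list(ids = ids, x = as.numeric(x), y = as.numeric(y),
                 bounds = as.numeric(bounds)),
            class = "spatial_frame")
}

#' Read a coordinates CSV (`individual_id,x,y`)
#' @param path file path.
#' @inheritParams spatial_frame
#' @return A [spatial_frame()].
#' @export
read_coordinates <- function(path, bounds = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "x", "y")
  if (!all(req %in% names(df)))
    stop("coordinates CSV needs columns: ", paste(req, collapse = ", "))
  spatial_frame(df$individual_id, df$x, df$y, bounds = bounds)
}

#' Pairwise Euclidean distances and clockwise bearings
#'
#' Bearings are measured clockwise from the plot's +Y axis ("north") and
#' reduced to the half-circle `[0, 180)` so that the bearing of the
#' undirected pair (i, j) equals that of (j, i). Pairs at identical
#' coordinates get an `NA` bearing and are listed in `colocated` so that
#' downstream log-distance regressions can exclude them.
#'
#' @param frame a [spatial_frame()].
#' @return A list with `dist` (n x n meters), `bearing` (n x n degrees,
#'   diagonal `NA`), and `colocated` (two-column matrix of zero-distance
#'   pairs).
#' @export
pairwise_geometry <- function(frame) {
  n <- length(frame$ids)
  if (n < 2L) stop("need at least 2 individuals")
  dx <- outer(frame$x, frame$x, "-")
  dy <- outer(frame$y, frame$y, "-")
  d <- sqrt(dx^2 + dy^2)
  brg <- (atan2(dx, dy) * 180 / pi) %% 180
  diag(brg) <- NA_real_
  zero <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
  brg[d == 0] <- NA_real_
  dimnames(d) <- dimnames(brg) <- list(frame$ids, frame$ids)
  list(dist = d, bearing = brg, colocated = zero)
}

#' Per-individual environmental covariates
#'
#' One row per individual: direct site factor (DSF, unitless light
#' availability fraction), soil cations (`na`, `k`, `mg`, one shared
#' concentration unit), soil anions (`n_total`, `p_total`), and moisture at
#' field capacity (fraction). Missing values stay `NA`; nothing is imputed.
#'
#' @param df data.frame with columns `individual_id`, `dsf`, `na`, `k`,
#'   `mg`, `n_total`, `p_total`, `field_capacity`.
#' @return An object of class `environment_table` (a validated data.frame).
#' @export
environment_table <- function(df) {
  req <- c("individual_id", "dsf", "na", "k", "mg", "n_total", "p_total",
           "field_capacity")
  if (!all(req %in% names(df)))
    stop("environment table needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$individual_id)) stop("one row per individual required")
  for (v in setdiff(req, "individual_id")) df[[v]] <- as.numeric(df[[v]])
  structure(df[req], class = c("environment_table", "data.frame"))
}

#' Read an environment CSV
#' @param path file path.
#' @return An [environment_table()].
#' @export
read_environment <- function(path) {
  environment_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Analysis configuration
#'
#' Bundles the tunable settings of the SGS analyses: the distance-class
#' width of the distogram, permutation counts for the distogram/Sp tests,
#' Mantel bearing tests and F_ST test, the number of bearing angles, and the
#' angular half-width of direction sectors.
#'
#' @param distance_class_width meters, width of distogram classes.
#' @param n_perm_distogram permutations for distogram envelopes and Sp.
#' @param n_perm_mantel permutations for bearing Mantel tests.
#' @param n_perm_fst permutations for the cohort F_ST test.
#' @param n_bearing_angles number of equidistant bearing angles in
#'   `[0, 180)`.
#' @param sector_halfwidth degrees; a direction sector spans `theta +/-`
#'   this half-width on the 180-degree circle.
#' @param rng_seed integer seed for all permutation draws.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(distance_class_width = 0.5,
                            n_perm_distogram = 9999L,
                            n_perm_mantel = 999L,
                            n_perm_fst = 500L,
                            n_bearing_angles = 128L,
                            sector_halfwidth = 15,
                            rng_seed = 1L) {
  stopifnot(distance_class_width > 0,
            n_perm_distogram >= 1, n_perm_mantel >= 1, n_perm_fst >= 1,
            n_bearing_angles >= 1,
            sector_halfwidth > 0, sector_halfwidth <= 90)
  structure(list(distance_class_width = distance_class_width,
                 n_perm_distogram = as.integer(n_perm_distogram),
                 n_perm_mantel = as.integer(n_perm_mantel),
                 n_perm_fst = as.integer(n_perm_fst),
                 n_bearing_angles = as.integer(n_bearing_angles),
                 sector_halfwidth = sector_halfwidth,
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}

# --- internal genotype accessors -------------------------------------------

# Allele dosage matrix: one column per (locus, allele) pair with values
# 0 / 0.5 / 1 (frequency of that allele within the individual), NA when the
# call is missing. Used by kinship, diversity, sPCA and AMOVA.
dosage_matrix <- function(g) {
  n <- n_ind(g); L <- length(g$loci)
  cols <- list(); locus_of <- integer(); allele_of <- integer()
  for (l in seq_len(L)) {
    a1 <- g$calls[, l, 1L]; a2 <- g$calls[, l, 2L]
    alleles <- sort(unique(c(a1[!is.na(a1)], a2[!is.na(a2)])))
    for (a in alleles) {
      v <- ((a1 == a) + (a2 == a)) / 2
      cols[[length(cols) + 1L]] <- v
      locus_of <- c(locus_of, l); allele_of <- c(allele_of, a)
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- g$ids
  colnames(X) <- paste0(g$loci[locus_of], ".", allele_of)
  list(X = X, locus = locus_of, allele = allele_of)
}

# Haploid dosage matrix from the plastid haplotype (one locus, one column
# per haplotype, values 0/1).
haplotype_dosage <- function(g) {
  if (is.null(g$haplotype)) stop("genotype table has no haplotype data")
  h <- g$haplotype
  haps <- sort(unique(h[!is.na(h)]))
  X <- sapply(haps, function(a) as.numeric(h == a))
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  rownames(X) <- g$ids
  colnames(X) <- paste0("hap.", haps)
  list(X = X, locus = rep(1L, ncol(X)), allele = seq_along(haps))
}
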