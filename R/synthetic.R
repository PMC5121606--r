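#' Simulation configuration for the biennial-cohort simulator
#'
#' Parameters of a forward-in-time model of a facultative-biennial plant
#' population: two reproductively interleaved lineages (odd/even flowering
#' years) on a rectangular plot, with limited seed dispersal, short-distance
#' pollen flow, maternal plastid inheritance, an inter-annual migrant rate
#' coupling the lineages, optional directional anisotropy of seed dispersal,
#' and optional environment-coupled establishment.
#'
#' @param plot_size numeric length-2, plot extent in meters (x, y).
#' @param n_per_cohort individuals sampled per output cohort.
#' @param n_loci number of unlinked diploid SSR-like loci.
#' @param n_alleles_per_locus alleles segregating per locus at initialization.
#' @param n_haplotypes plastid haplotypes at initialization.
#' @param seed_kernel_mean meters; mean of the exponential seed-dispersal
#'   kernel (mother-to-offspring displacement).
#' @param pollen_kernel_mean meters; scale of the exponential distance decay
#'   of pollination probability.
#' @param selfing_rate probability an offspring is selfed.
#' @param migrant_fraction probability an offspring flowers with the other
#'   lineage (inter-annual migration between consecutive cohorts).
#' @param anisotropy_ratio `a >= 1`; the seed-displacement component along
#'   `anisotropy_axis` is divided by `a` (1 = isotropic).
#' @param anisotropy_axis degrees clockwise from the +Y axis.
#' @param env_coupling `gamma >= 0`; establishment is accepted with
#'   probability `exp(-gamma * |g - e|)` where `g` is the allele dosage at a
#'   designated locus and `e` the unit-scaled light (DSF) surface.
#' @param burn_in_generations generations evolved before sampling.
#' @param dsf_base,dsf_cline,dsf_noise_sd light surface: baseline, linear
#'   increase across the plot's X extent, and SD of the smooth noise field.
#' @param env_length_scale meters; correlation length of all smooth
#'   environmental noise fields.
#' @param rng_seed integer seed; identical seeds give identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(plot_size = c(20, 20),
                       n_per_cohort = 100L,
                       n_loci = 10L,
                       n_alleles_per_locus = 10L,
                       n_haplotypes = 5L,
                       seed_kernel_mean = 0.3,
                       pollen_kernel_mean = 2.0,
                       selfing_rate = 0.05,
                       migrant_fraction = 0.15,
                       anisotropy_ratio = 1,
                       anisotropy_axis = 0,
                       env_coupling = 0,
                       burn_in_generations = 20L,
                       dsf_base = 0.25,
                       dsf_cline = 0.5,
                       dsf_noise_sd = 0.12,
                       env_length_scale = 3,
                       rng_seed = 1L) {
  stopifnot(length(plot_size) == 2L, all(plot_size > 0),
            n_per_cohort >= 2, n_loci >= 1, n_alleles_per_locus >= 2,
            n_haplotypes >= 1,
            seed_kernel_mean > 0, pollen_kernel_mean > 0,
            selfing_rate >= 0, selfing_rate <= 1,
            migrant_fraction >= 0, migrant_fraction <= 1,
            anisotropy_ratio >= 1, env_coupling >= 0,
            burn_in_generations >= 1, env_length_scale > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate smooth environmental surfaces over the plot
#'
#' Builds deterministic (given the seed) surface functions: light
#' availability (DSF) as a linear cline along X plus a smooth Gaussian noise
#' field, clipped to `[0, 1]`, and independent smooth patchy fields for soil
#' cations (Na, K, Mg), anions (total N, P) and field capacity. Units are
#' nominal concentrations; downstream models standardize them anyway.
#'
#' @param config a [sim_config()].
#' @return A list of functions of `(x, y)`: `dsf`, `na`, `k`, `mg`,
#'   `n_total`, `p_total`, `field_capacity`, plus `dsf_unit`, the DSF
#'   surface rescaled to `[0, 1]` over the plot (used by establishment
#'   coupling).
#' @export
make_environment <- function(config) {
  set.seed(stage_seed(config$rng_seed, "environment"))
  ls <- config$env_length_scale
  noise <- random_surface(ls, config$dsf_noise_sd)
  px <- config$plot_size[1]
  dsf_raw <- function(x, y) {
    config$dsf_base + config$dsf_cline * x / px + noise(x, y)
  }
  dsf <- function(x, y) pmin(1, pmax(0, dsf_raw(x, y)))
  # unit-scaling constants from a fixed evaluation grid
  gx <- seq(0, px, length.out = 25L)
  gy <- seq(0, config$plot_size[2], length.out = 25L)
  gr <- expand.grid(x = gx, y = gy)
  dv <- dsf(gr$x, gr$y)
  lo <- min(dv); hi <- max(dv)
  dsf_unit <- if (hi > lo) {
    function(x, y) pmin(1, pmax(0, (dsf(x, y) - lo) / (hi - lo)))
  } else {
    function(x, y) rep(0.5, length(x))
  }
  patchy <- function(base, amp) {
    f <- random_surface(ls, amp)
    function(x, y) pmax(0, base + f(x, y))
  }
  list(dsf = dsf, dsf_unit = dsf_unit,
       na = patchy(5, 1.2), k = patchy(2, 0.5), mg = patchy(1, 0.3),
       n_total = patchy(0.3, 0.08), p_total = patchy(0.05, 0.015),
       field_capacity = {
         f <- random_surface(ls, 0.05)
         function(x, y) pmin(1, pmax(0.02, 0.25 + f(x, y)))
       })
}

# Compress a displacement (dx, dy) along the anisotropy axis (degrees from +Y).
compress_displacement <- function(dx, dy, axis_deg, ratio) {
  if (ratio == 1) return(cbind(dx, dy))
  th <- axis_deg * pi / 180
  ax <- sin(th); ay <- cos(th)
  proj <- dx * ax + dy * ay
  cbind(dx + (1 / ratio - 1) * proj * ax,
        dy + (1 / ratio - 1) * proj * ay)
}

# Reflect coordinates into [0, limit].
reflect_into <- function(v, limit) {
  v <- abs(v)
  v <- v %% (2 * limit)
  ifelse(v > limit, 2 * limit - v, v)
}

#' Forward simulation of two consecutive flowering cohorts
#'
#' Two lineages (odd/even flowering years) evolve for
#' `burn_in_generations` with non-overlapping generations. Each offspring
#' draws its mother uniformly from the lineage's adults, its father by
#' distance-decaying pollen flow (`exp(-d / pollen_kernel_mean)`) or selfing,
#' is displaced from the mother by an exponential seed-dispersal step with
#' uniform direction (optionally compressed along the anisotropy axis, with
#' reflective plot boundaries), inherits its plastid haplotype maternally,
#' and — when `env_coupling > 0` — establishes with probability
#' `exp(-gamma |g - e(x, y)|)` tied to a designated locus. With probability
#' `migrant_fraction` an offspring is recruited into the other lineage's
#' next cohort. The final two generations are subsampled to `n_per_cohort`
#' each and labelled `"2010"` / `"2011"`.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_output` with elements `genotypes`
#'   ([genotype_table()]), `frame` ([spatial_frame()]), `environment`
#'   ([environment_table()]), and `truth` (the configuration, realized
#'   migrant counts, final-generation pedigree with parental genotypes, and
#'   the environment surfaces).
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  env <- make_environment(config)
  set.seed(stage_seed(config$rng_seed, "forward-simulation"))
  K <- max(config$n_per_cohort, ceiling(1.2 * config$n_per_cohort))
  px <- config$plot_size[1]; py <- config$plot_size[2]
  L <- config$n_loci

  new_pop <- function(k) list(
    x = stats::runif(k, 0, px),
    y = stats::runif(k, 0, py),
    geno = array(sample.int(config$n_alleles_per_locus, k * L * 2L,
                            replace = TRUE), dim = c(k, L, 2L)),
    hap = sample.int(config$n_haplotypes, k, replace = TRUE),
    mig = rep(FALSE, k),
    mother = rep(NA_integer_, k), father = rep(NA_integer_, k),
    dx = rep(NA_real_, k), dy = rep(NA_real_, k))

  pops <- list(A = new_pop(K), B = new_pop(K))

  # anisotropy acts on gene flow as a whole: the axis-parallel component of
  # a seed displacement is divided by `a`, and pollination probability uses
  # the equivalently stretched distance metric (moving along the axis costs
  # `a` times more), so direction-dependent resistance applies to both seed
  # and pollen movement
  th_ax <- config$anisotropy_axis * pi / 180
  axv <- c(sin(th_ax), cos(th_ax))
  aniso_dist <- function(dx, dy) {
    if (config$anisotropy_ratio == 1) return(sqrt(dx^2 + dy^2))
    par <- dx * axv[1L] + dy * axv[2L]
    px <- dx - par * axv[1L]; py <- dy - par * axv[2L]
    sqrt(px^2 + py^2 + (config$anisotropy_ratio * par)^2)
  }

  breed_one <- function(pop) {
    k <- length(pop$x)
    repeat {
      m <- sample.int(k, 1L)
      if (stats::runif(1) < config$selfing_rate) {
        f <- m
      } else {
        d <- aniso_dist(pop$x - pop$x[m], pop$y - pop$y[m])
        f <- sample.int(k, 1L, prob = exp(-d / config$pollen_kernel_mean))
      }
      r <- stats::rexp(1L, rate = 1 / config$seed_kernel_mean)
      u <- stats::runif(1L, 0, 2 * pi)  # clockwise from +Y
      disp <- compress_displacement(r * sin(u), r * cos(u),
                                    config$anisotropy_axis,
                                    config$anisotropy_ratio)
      x <- reflect_into(pop$x[m] + disp[1L], px)
      y <- reflect_into(pop$y[m] + disp[2L], py)
      geno <- matrix(NA_integer_, L, 2L)
      pick <- sample(c(1L, 2L), L, replace = TRUE)
      geno[, 1L] <- pop$geno[cbind(m, seq_len(L), pick)]
      pick <- sample(c(1L, 2L), L, replace = TRUE)
      geno[, 2L] <- pop$geno[cbind(f, seq_len(L), pick)]
      if (config$env_coupling > 0) {
        g <- sum(geno[1L, ] == 1L) / 2  # dosage of allele 1 at locus 1
        e <- env$dsf_unit(x, y)
        if (stats::runif(1) > exp(-config$env_coupling * abs(g - e))) next
      }
      return(list(x = x, y = y, geno = geno, hap = pop$hap[m],
                  mother = m, father = f, dx = disp[1L], dy = disp[2L]))
    }
  }

  realized_migrants <- c(A = 0L, B = 0L)
  for (gen in seq_len(config$burn_in_generations)) {
    off <- list(A = vector("list", K), B = vector("list", K))
    dest <- list(A = character(K), B = character(K))
    for (lin in c("A", "B")) {
      for (i in seq_len(K)) {
        off[[lin]][[i]] <- breed_one(pops[[lin]])
        dest[[lin]][i] <- if (stats::runif(1) < config$migrant_fraction) {
          setdiff(c("A", "B"), lin)
        } else lin
      }
    }
    nxt <- list()
    mig_count <- c(A = 0L, B = 0L)
    for (lin in c("A", "B")) {
      other <- setdiff(c("A", "B"), lin)
      natives <- off[[lin]][dest[[lin]] == lin]
      migrants <- off[[other]][dest[[other]] == lin]
      pool <- c(natives, migrants)
      from_other <- c(rep(FALSE, length(natives)), rep(TRUE, length(migrants)))
      src <- c(rep(lin, length(natives)), rep(other, length(migrants)))
      if (length(pool) == 0L)
        stop("population extinction during burn-in; increase n_per_cohort")
      take <- if (length(pool) >= K) sample.int(length(pool), K)
              else sample.int(length(pool), K, replace = TRUE)
      sel <- pool[take]
      nxt[[lin]] <- list(
        x = vapply(sel, `[[`, 0, "x"),
        y = vapply(sel, `[[`, 0, "y"),
        geno = array(unlist(lapply(sel, `[[`, "geno")), dim = c(L, 2L, K)),
        hap = vapply(sel, `[[`, 0L, "hap"),
        mig = from_other[take],
        mother = vapply(sel, `[[`, 0L, "mother"),
        father = vapply(sel, `[[`, 0L, "father"),
        src = src[take],
        dx = vapply(sel, `[[`, 0, "dx"),
        dy = vapply(sel, `[[`, 0, "dy"))
      nxt[[lin]]$geno <- aperm(nxt[[lin]]$geno, c(3L, 1L, 2L))
      mig_count[lin] <- sum(nxt[[lin]]$mig)
    }
    parents <- pops  # kept for the pedigree of the final generation
    pops <- nxt
    realized_migrants <- mig_count
  }

  # sample the output cohorts
  keep <- lapply(pops, function(p) sort(sample.int(K, config$n_per_cohort)))
  labs <- c(A = "2010", B = "2011")
  ids <- character(); cohort <- character()
  xs <- numeric(); ys <- numeric()
  calls <- array(NA_integer_,
                 dim = c(2L * config$n_per_cohort, L, 2L))
  hap <- integer(); ped <- list()
  row <- 0L
  for (lin in c("A", "B")) {
    p <- pops[[lin]]; kp <- keep[[lin]]
    for (i in kp) {
      row <- row + 1L
      ids <- c(ids, sprintf("%s_%03d", labs[lin], i))
      cohort <- c(cohort, labs[lin])
      xs <- c(xs, p$x[i]); ys <- c(ys, p$y[i])
      calls[row, , ] <- p$geno[i, , ]
      hap <- c(hap, p$hap[i])
      ped[[row]] <- list(id = sprintf("%s_%03d", labs[lin], i),
                         lineage = lin, migrant = p$mig[i],
                         source_lineage = p$src[i],
                         mother = p$mother[i], father = p$father[i],
                         dx = p$dx[i], dy = p$dy[i])
    }
  }
  genotypes <- genotype_table(ids, cohort, calls, sprintf("L%02d", seq_len(L)),
                              haplotype = hap)
  frame <- spatial_frame(ids, xs, ys, bounds = c(0, px, 0, py))
  envtab <- environment_table(data.frame(
    individual_id = ids,
    dsf = env$dsf(xs, ys), na = env$na(xs, ys), k = env$k(xs, ys),
    mg = env$mg(xs, ys), n_total = env$n_total(xs, ys),
    p_total = env$p_total(xs, ys),
    field_capacity = env$field_capacity(xs, ys),
    stringsAsFactors = FALSE))
  pedigree <- do.call(rbind, lapply(ped, function(e)
    data.frame(id = e$id, lineage = e$lineage, migrant = e$migrant,
               source_lineage = e$source_lineage, mother = e$mother,
               father = e$father, dx = e$dx, dy = e$dy,
               stringsAsFactors = FALSE)))
  truth <- list(config = unclass(config)[setdiff(names(config), "")],
                realized_migrants = as.list(realized_migrants),
                realized_migrant_fraction =
                  sum(realized_migrants) / (2 * K),
                pedigree = pedigree,
                parent_genotypes = lapply(parents, `[[`, "geno"),
                parent_haplotypes = lapply(parents, `[[`, "hap"),
                surfaces = env)
  structure(list(genotypes = genotypes, frame = frame,
                 environment = envtab, truth = truth),
            class = "sim_output")
}

#' Write a simulation to plain-text files
#'
#' Emits `genotypes.csv`, `genotypes.gen` (GENEPOP), `coords.csv`,
#' `environment.csv` and `truth.json` (configuration and realized migrant
#' numbers; the pedigree is omitted from the JSON).
#'
#' @param sim a `sim_output` from [simulate_cohorts()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.csv"), "csv")
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.gen"), "genepop")
  write_tsv_file(data.frame(individual_id = sim$frame$ids,
                            x = sim$frame$x, y = sim$frame$y),
                 file.path(dir, "coords.tsv"))
  utils::write.csv(data.frame(individual_id = sim$frame$ids,
                              x = sim$frame$x, y = sim$frame$y),
                   file.path(dir, "coords.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(sim$environment),
                   file.path(dir, "environment.csv"), row.names = FALSE)
  tr <- sim$truth
  write_json_file(list(config = tr$config[!vapply(tr$config, is.function, TRUE)],
                       realized_migrants = tr$realized_migrants,
                       realized_migrant_fraction = tr$realized_migrant_fraction),
                  file.path(dir, "truth.json"))
  invisible(dir)
}
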