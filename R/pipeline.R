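#' Run the full SGS analysis pipeline
#'
#' Config-driven end-to-end run: obtain inputs (either by forward
#' simulation or from genotype/coordinate/environment files), then per-locus
#' diversity with cohort F_ST and AMOVA, pairwise kinship, isotropic
#' distograms and Sp within each cohort and between cohorts, bearing
#' correlograms with sector-restricted Sp at the strongest/weakest
#' directions, sPCA with global/local tests, and lagged SAR model averaging
#' of the two leading sPCA scores on the environmental predictors. One
#' master seed is fanned out to named per-stage substreams, so adding a
#' stage never perturbs another stage's draws. Artifacts are plain TSV/JSON
#' under `out_dir`; `report.json` (deterministic for a given config and
#' seed) and `report.md` (with stage timings) summarize the run.
#'
#' @param config a list, or path to a YAML file, with optional entries
#'   `simulation` ([sim_config()] fields), `inputs` (paths `genotypes`,
#'   `format`, `coords`, `environment`), `analysis` ([analysis_config()]
#'   fields), `stages` (character subset of
#'   `c("diversity","isotropic","anisotropic","spca","sar")`), `seed`,
#'   `density`.
#' @param out_dir output directory for artifacts.
#' @param dry_run validate the configuration and inputs without computing.
#' @return A list of class `pipeline_report`; its `status` element maps
#'   stage name to `"ok"`, `"failed"` or `"skipped"`.
#' @export
run_pipeline <- function(config, out_dir, dry_run = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  acfg <- do.call(analysis_config,
                  c(config$analysis %||% list(),
                    if (is.null(config$analysis$rng_seed))
                      list(rng_seed = stage_seed(seed, "analysis"))))
  stages <- config$stages %||%
    c("diversity", "isotropic", "anisotropic", "spca", "sar")
  has_sim <- !is.null(config$simulation)
  has_inputs <- !is.null(config$inputs)
  if (!has_sim && !has_inputs)
    stop("config must contain either 'simulation' or 'inputs'")

  if (!dry_run) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  status <- list(); headline <- list(); timings <- list(); artifacts <- list()

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    status[[name]] <<- if (res$ok) "ok" else paste0("failed: ", res$msg)
    if (res$ok) res$value else NULL
  }

  # --- inputs ---------------------------------------------------------------
  if (has_sim) {
    scfg <- do.call(sim_config, c(config$simulation,
                                  if (is.null(config$simulation$rng_seed))
                                    list(rng_seed = stage_seed(seed, "simulate"))))
    if (dry_run) return(invisible(structure(
      list(status = list(config = "ok"), dry_run = TRUE),
      class = "pipeline_report")))
    sim <- run_stage("simulate", function() simulate_cohorts(scfg))
    if (is.null(sim)) stop("simulation stage failed: ", status$simulate)
    g <- sim$genotypes; frame <- sim$frame; envtab <- sim$environment
    write_simulation(sim, file.path(out_dir, "inputs"))
    artifacts$inputs <- file.path(out_dir, "inputs")
  } else {
    inp <- config$inputs
    g <- read_genotypes(inp$genotypes, inp$format %||% "csv",
                        cohort_labels = inp$cohort_labels)
    frame <- read_coordinates(inp$coords)
    envtab <- if (!is.null(inp$environment)) read_environment(inp$environment)
    if (!identical(sort(frame$ids), sort(g$ids)))
      stop("genotype and coordinate ids do not match")
    ord <- match(g$ids, frame$ids)
    frame <- spatial_frame(frame$ids[ord], frame$x[ord], frame$y[ord],
                           frame$bounds)
    if (dry_run) return(invisible(structure(
      list(status = list(config = "ok", inputs = "ok"), dry_run = TRUE),
      class = "pipeline_report")))
    status$inputs <- "ok"
  }
  cohorts <- levels(g$cohort)

  geom <- pairwise_geometry(frame)

  # --- diversity ------------------------------------------------------------
  if ("diversity" %in% stages) {
    div <- run_stage("diversity", function() {
      set.seed(stage_seed(seed, "diversity"))
      summ <- locus_summaries(g)
      fst <- fst_between_cohorts(g, n_perm = acfg$n_perm_fst)
      amv <- amova_chord(g, n_perm = acfg$n_perm_fst)
      list(summaries = summ, fst = fst, amova = amv)
    })
    if (!is.null(div)) {
      write_tsv_file(div$summaries, file.path(out_dir, "locus_summaries.tsv"))
      write_json_file(list(fst = div$fst$fst, fst_p = div$fst$p_value,
                           amova_sigma2_among = div$amova$sigma2_among,
                           amova_p = div$amova$p_value),
                      file.path(out_dir, "differentiation.json"))
      headline$fst <- div$fst$fst; headline$fst_p <- div$fst$p_value
      headline$amova_sigma2 <- div$amova$sigma2_among
      headline$amova_p <- div$amova$p_value
      artifacts$diversity <- c("locus_summaries.tsv", "differentiation.json")
    }
  }

  # --- kinship ---------------------------------------------------------------
  kin <- run_stage("kinship", function() kinship_matrix(g, "ssr", "pooled"))
  if (is.null(kin)) {
    report <- structure(list(config = config, status = status,
                             headline = headline, artifacts = artifacts,
                             timings = timings), class = "pipeline_report")
    finish_report(report, out_dir)
    return(report)
  }
  write_kinship(kin, file.path(out_dir, "kinship_ssr.tsv"))
  artifacts$kinship <- "kinship_ssr.tsv"

  # --- isotropic --------------------------------------------------------------
  if ("isotropic" %in% stages) {
    iso <- run_stage("isotropic", function() {
      runs <- list()
      for (lab in cohorts)
        runs[[paste0("within_", lab)]] <-
          list(dist = distogram(kin, geom$dist, "within", lab, acfg),
               sp = sp_statistic(kin, geom$dist, "within", lab, acfg,
                                 density = config$density))
      runs$between_cohorts <-
        list(dist = distogram(kin, geom$dist, "between", config = acfg),
             sp = sp_statistic(kin, geom$dist, "between", config = acfg,
                               density = config$density))
      runs$t_test <- compare_cohorts(runs[[paste0("within_", cohorts[1])]]$sp,
                                     runs[[paste0("within_", cohorts[2])]]$sp,
                                     n_loci = length(kin$den))
      runs
    })
    if (!is.null(iso)) {
      for (nm in setdiff(names(iso), "t_test"))
        write_tsv_file(iso[[nm]]$dist,
                       file.path(out_dir, paste0("distogram_", nm, ".tsv")))
      sp_tab <- lapply(setdiff(names(iso), "t_test"), function(nm) {
        s <- iso[[nm]]$sp
        list(mode = nm, b_F = s$b_F, se_bF = s$se_bF, F_1 = s$F_1,
             se_F1 = s$se_F1, Sp = s$Sp, se_Sp = s$se_Sp, p_Sp = s$p_Sp)
      })
      write_json_file(sp_tab, file.path(out_dir, "sp_results.json"))
      write_tsv_file(iso$t_test, file.path(out_dir, "sp_cohort_ttest.tsv"))
      headline$sp <- lapply(sp_tab, function(s) s[c("mode", "Sp", "p_Sp")])
      artifacts$isotropic <- c("sp_results.json", "sp_cohort_ttest.tsv")
    }
  }

  # --- anisotropic ------------------------------------------------------------
  if ("anisotropic" %in% stages) {
    aniso <- run_stage("anisotropic", function() {
      out <- list()
      for (lab in cohorts) {
        sel <- g$cohort == lab
        kc <- kinship_matrix(subset_genotypes(g, sel), "ssr", "pooled")
        sub <- spatial_frame(frame$ids[sel], frame$x[sel], frame$y[sel],
                             frame$bounds)
        gc <- pairwise_geometry(sub)
        bc <- bearing_correlogram(kc, gc$dist, gc$bearing, acfg)
        out[[lab]] <- list(
          correlogram = bc,
          sp_s = sector_sp(kc, gc$dist, gc$bearing, bc$theta_s,
                           "within", lab, acfg),
          sp_w = sector_sp(kc, gc$dist, gc$bearing, bc$theta_w,
                           "within", lab, acfg))
      }
      out
    })
    if (!is.null(aniso)) {
      for (lab in cohorts)
        write_tsv_file(aniso[[lab]]$correlogram$profile,
                       file.path(out_dir, paste0("bearing_", lab, ".tsv")))
      js <- lapply(aniso, function(a) list(
        theta_s = a$correlogram$theta_s, r_s = a$correlogram$r_s,
        theta_w = a$correlogram$theta_w, r_w = a$correlogram$r_w,
        sp_theta_s = a$sp_s$Sp, sp_theta_w = a$sp_w$Sp))
      write_json_file(js, file.path(out_dir, "anisotropy.json"))
      headline$anisotropy <- js
      artifacts$anisotropic <- "anisotropy.json"
    }
  }

  # --- sPCA -------------------------------------------------------------------
  spca_runs <- NULL
  if (any(c("spca", "sar") %in% stages)) {
    spca_runs <- run_stage("spca", function() {
      out <- list()
      for (lab in cohorts) {
        sel <- g$cohort == lab
        sub <- spatial_frame(frame$ids[sel], frame$x[sel], frame$y[sel],
                             frame$bounds)
        net <- build_network(sub, "raw")
        fit <- spca_fit(g, net, lab)
        set.seed(stage_seed(seed, paste0("spca-global-", lab)))
        gl <- global_local_test(g, net, lab, "global",
                                n_perm = acfg$n_perm_mantel)
        set.seed(stage_seed(seed, paste0("spca-local-", lab)))
        lc <- global_local_test(g, net, lab, "local",
                                n_perm = acfg$n_perm_mantel)
        out[[lab]] <- list(fit = fit, global = gl, local = lc)
      }
      out
    })
    if (!is.null(spca_runs)) {
      for (lab in cohorts) {
        f <- spca_runs[[lab]]$fit
        write_tsv_file(data.frame(individual_id = rownames(f$scores),
                                  f$scores[, 1:2, drop = FALSE]),
                       file.path(out_dir, paste0("spca_scores_", lab, ".tsv")))
      }
      js <- lapply(spca_runs, function(s) list(
        eigenvalues = s$fit$eigenvalues[seq_len(min(5, length(s$fit$eigenvalues)))],
        global_max_t = s$global$statistic, global_p = s$global$p_value,
        local_max_t = s$local$statistic, local_p = s$local$p_value))
      write_json_file(js, file.path(out_dir, "spca_tests.json"))
      headline$spca <- js
      artifacts$spca <- "spca_tests.json"
    }
  }

  # --- SAR --------------------------------------------------------------------
  if ("sar" %in% stages && !is.null(spca_runs) && !is.null(envtab)) {
    sar <- run_stage("sar", function() {
      out <- list()
      for (lab in cohorts) {
        sel <- g$cohort == lab
        sub <- spatial_frame(frame$ids[sel], frame$x[sel], frame$y[sel],
                             frame$bounds)
        net <- build_network(sub, "row")
        ep <- build_env_predictors(
          environment_table(as.data.frame(envtab)[sel, ]))
        set.seed(stage_seed(seed, paste0("sar-", lab)))
        for (pc in 1:2) {
          G <- spca_runs[[lab]]$fit$scores[, pc]
          out[[paste0(lab, "_PC", pc)]] <- model_select_average(G, ep, net)
        }
      }
      out
    })
    if (!is.null(sar)) {
      tabs <- lapply(names(sar), function(nm)
        cbind(response = nm, sar[[nm]]$table,
              rho = sar[[nm]]$rho$estimate))
      write_tsv_file(do.call(rbind, tabs), file.path(out_dir, "sar_averages.tsv"))
      headline$sar <- lapply(sar, function(s) list(
        rho = s$rho$estimate,
        top_predictor = s$table$predictor[which.max(s$table$w_plus)],
        top_w_plus = max(s$table$w_plus)))
      artifacts$sar <- "sar_averages.tsv"
    }
  } else if ("sar" %in% stages) {
    status$sar <- "skipped"
  }

  report <- structure(list(config = config_echo(config),
                           status = status, headline = headline,
                           artifacts = artifacts, timings = timings),
                      class = "pipeline_report")
  finish_report(report, out_dir)
  report
}

config_echo <- function(config) {
  rapply(config, function(x) if (is.function(x)) NULL else x, how = "replace")
}

finish_report <- function(report, out_dir) {
  # report.json is deterministic for a given config + seed: timings go to
  # report.md only
  write_json_file(report[c("config", "status", "headline", "artifacts")],
                  file.path(out_dir, "report.json"))
  md <- c("# finesgs pipeline report", "",
          "## Stage status", "",
          sprintf("- %s: %s (%.2f s)", names(report$status),
                  unlist(report$status),
                  vapply(names(report$status), function(n)
                    report$timings[[n]] %||% NA_real_, 0)),
          "", "## Headline numbers", "",
          sprintf("```json\n%s\n```",
                  jsonlite::toJSON(report$headline, auto_unbox = TRUE,
                                   digits = NA, pretty = TRUE)))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  for (nm in names(x$status)) cat(sprintf("  %-12s %s\n", nm, x$status[[nm]]))
  invisible(x)
}
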