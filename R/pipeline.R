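# End-to-end pipeline: simulate -> connectivity -> edge stats ->
# TFCE / NBS -> COI analysis, with provenance-carrying text artifacts.

#' Pipeline configuration
#'
#' @param scenario a [simulation_scenario()] (or path to a scenario JSON).
#' @param atlas a [network_atlas()] (or path to an atlas JSON); default
#'   the packaged 8-network atlas.
#' @param contrasts list of 2-vectors of group labels to compare with
#'   TFCE (default `list(c("HC","AD"), c("HC","MCI"))`).
#' @param params a [tfce_params()].
#' @param n_permutations permutations per contrast (default 1000).
#' @param nbs_threshold edge |t| threshold for the NBS comparator
#'   (default 3); set to `NULL` to skip NBS.
#' @param scrub apply outlier-scan scrubbing with the default
#'   [scrubbing_rule()] using generated nuisance traces (default `TRUE`).
#' @param alpha significance level used to pick clusters of interest for
#'   the downstream ANOVA/CDR stage (applied to cluster-level
#'   `p_uncorrected`; default 0.05).
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it via [split_seed()]. Defaults to `scenario$seed`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = simulation_scenario(),
                            atlas = default_atlas(),
                            contrasts = list(c("HC", "AD"), c("HC", "MCI")),
                            params = tfce_params(),
                            n_permutations = 1000L,
                            nbs_threshold = 3,
                            scrub = TRUE,
                            alpha = 0.05,
                            seed = NULL) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  if (is.character(atlas)) atlas <- read_atlas(atlas)
  stopifnot(inherits(scenario, "simulation_scenario"),
            inherits(atlas, "network_atlas"))
  if (is.null(seed)) seed <- scenario$seed
  structure(list(scenario = scenario, atlas = atlas, contrasts = contrasts,
                 params = params, n_permutations = as.integer(n_permutations),
                 nbs_threshold = nbs_threshold, scrub = isTRUE(scrub),
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  # provenance hash over the canonical JSON serialization of the config
  js <- jsonlite::toJSON(list(scenario = unclass(config$scenario),
                              atlas_labels = config$atlas$roi_labels,
                              contrasts = config$contrasts,
                              params = unclass(config$params),
                              n_permutations = config$n_permutations,
                              nbs_threshold = config$nbs_threshold,
                              scrub = config$scrub, alpha = config$alpha,
                              seed = config$seed),
                         auto_unbox = TRUE, digits = NA)
  sprintf("%08x", fnv1a32(as.character(js)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> scrub -> connectivity -> edge statistics ->
#' TFCE (+ NBS) -> COI ANOVA and CDR correlation, writing delimited-text
#' artifacts plus JSON sidecars under `out_dir`. Artifacts carry
#' provenance (config hash, seed, package version). Identical configs
#' yield byte-identical artifacts (the stage log, which carries
#' timings, goes to a separate `pipeline.log`).
#'
#' Any stage failure is re-signalled with the stage name prefixed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose print per-stage progress (default `TRUE`).
#' @return invisibly, a list with the fitted objects: `design`,
#'   `tfce` (one `tfce_test` per contrast), `nbs`, `coi` (per-cluster
#'   `coi_summary`), `cdr` (per-cluster/group `correlation_result`),
#'   `paths`.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  cat(sprintf("pipeline started %s\n", format(Sys.time())), file = logf)
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stopf("[%s] %s", name, conditionMessage(e))),
      warning = function(w) {
        cat(sprintf("  warning [%s]: %s\n", name, conditionMessage(w)),
            file = logf, append = TRUE)
        invokeRestart("muffleWarning")
      })
    dt <- proc.time()[["elapsed"]] - t0
    cat(sprintf("stage %-12s %.2fs\n", name, dt), file = logf, append = TRUE)
    if (verbose) message(sprintf("[%s] done in %.2fs", name, dt))
    res
  }

  sc <- config$scenario
  atlas <- config$atlas

  cohort <- t_stage("simulate", generate_cohort(sc, atlas))
  design <- cohort$design
  ts_list <- cohort$timeseries

  if (config$scrub) {
    nuis <- t_stage("nuisance", generate_nuisance(sc))
    ts_list <- t_stage("scrub", lapply(ts_list, function(ts)
      scrub(ts, nuis[[ts$subject_id]]$fd, nuis[[ts$subject_id]]$global_signal)))
  }

  zs <- t_stage("connect", lapply(ts_list, connectivity))

  t_stage("write-inputs", {
    write_subject_table(design, file.path(out_dir, "subjects.tsv"))
    invisible(NULL)
  })

  fits <- list(); nbs_fits <- list()
  for (ct in config$contrasts) {
    tag <- paste0(ct[1], "-", ct[2])
    fits[[tag]] <- t_stage(paste0("tfce:", tag),
      tfce_test(zs, design, ct, params = config$params,
                n_permutations = config$n_permutations,
                seed = split_seed(config$seed, paste0("perm:", tag)),
                atlas = atlas))
    rep_df <- extract_report(fits[[tag]], atlas)
    write_report(rep_df, file.path(out_dir, sprintf("report_%s.tsv", tag)))
    if (!is.null(config$nbs_threshold))
      nbs_fits[[tag]] <- t_stage(paste0("nbs:", tag),
        nbs(zs, design, ct, edge_threshold = config$nbs_threshold,
            n_permutations = config$n_permutations,
            seed = split_seed(config$seed, paste0("nbs:", tag))))
  }

  # clusters of interest: significant clusters across contrasts
  coi <- list(); cdrres <- list()
  t_stage("coi", {
    idx <- 0
    for (tag in names(fits)) {
      for (cl in fits[[tag]]$clusters) {
        if (cl$p_uncorrected >= config$alpha) next
        idx <- idx + 1
        cid <- sprintf("COI%d", idx)
        mz <- coi_mean_z(cl, zs)
        coi[[cid]] <- coi_anova(mz, design, cluster_id = cid)
        for (g in setdiff(unique(design$group_of), "HC")) {
          cdrres[[paste0(cid, ":", g)]] <-
            cdr_correlation(mz, design = design, group = g, cluster_id = cid)
        }
      }
    }
    invisible(NULL)
  })

  t_stage("write-results", {
    write_pipeline_results(config, fits, nbs_fits, coi, cdrres, out_dir)
    invisible(NULL)
  })
  cat(sprintf("pipeline finished %s\n", format(Sys.time())),
      file = logf, append = TRUE)
  invisible(list(design = design, z_matrices = zs, tfce = fits,
                 nbs = nbs_fits, coi = coi, cdr = cdrres,
                 paths = list(out_dir = out_dir)))
}

write_pipeline_results <- function(config, fits, nbs_fits, coi, cdrres, out_dir) {
  res <- list(
    provenance = list(config_hash = config_hash(config), seed = config$seed,
                      package_version = as.character(utils::packageVersion("conntfce"))),
    tfce = lapply(fits, function(f) list(
      contrast = f$contrast, n_permutations = f$n_permutations,
      cluster_threshold = f$cluster_threshold,
      global_peak = f$global_peak, global_peak_p_fwe = f$global_peak_p_fwe,
      clusters = lapply(f$clusters, function(cl)
        list(n_edges = nrow(cl$edges), mass = cl$mass,
             p_uncorrected = cl$p_uncorrected, peak_tfce = cl$peak_tfce,
             peak_p_fwe = cl$peak_p_fwe, sign = cl$sign,
             networks_involved = cl$networks_involved)))),
    nbs = lapply(nbs_fits, function(f) list(
      contrast = f$contrast, threshold = f$threshold,
      components = lapply(f$components, function(cp)
        list(size = cp$size, mass = cp$mass, p_fwe = cp$p_fwe, sign = cp$sign)))))
  jsonlite::write_json(res, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(coi)) {
    coidf <- do.call(rbind, lapply(coi, function(s) {
      pw <- s$pairwise
      data.frame(cluster_id = s$cluster_id,
                 anova_f = s$anova_f, anova_p = s$anova_p,
                 pair = paste(pw$group_a, pw$group_b, sep = "-"),
                 t = pw$t, p = pw$p, p_bonferroni = pw$p_bonferroni,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(format_numeric(coidf), file.path(out_dir, "coi_anova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(cdrres)) {
    cdf <- do.call(rbind, lapply(cdrres, function(r)
      data.frame(cluster_id = r$cluster_id, group = r$group, R = r$R,
                 R2 = r$R2, p = r$p, n = r$n,
                 passes_reporting_rule = r$passes_reporting_rule,
                 stringsAsFactors = FALSE)))
    utils::write.table(format_numeric(cdf), file.path(out_dir, "cdr_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

format_numeric <- function(df) {
  for (cc in names(df)) if (is.numeric(df[[cc]]) && !is.integer(df[[cc]]))
    df[[cc]] <- sprintf("%.17g", df[[cc]])
  df
}
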