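#' Simulation scenario for synthetic resting-state cohorts
#'
#' Defines the generative conditions for a multi-group cohort of ROI BOLD
#' time series: one latent Gaussian signal per network shared by its ROIs
#' with a common loading, AR(1) temporal autocorrelation on latent and
#' unique components, a planted cluster of edges whose population Fisher-z
#' connectivity is reduced in one diagnostic group, and clinical scores
#' (CDR, an MMSE-like score) coupled linearly to each subject's mean
#' planted-edge z.
#'
#' With loading \eqn{\lambda}, two same-network ROIs have population
#' correlation \eqn{\lambda^2} (unit-variance shared signal plus
#' independent noise of variance \eqn{1-\lambda^2}).
#'
#' @param n_per_group named integer vector of group sizes. Default mirrors
#'   the three-group cohort HC = 31, MCI = 31, AD = 33.
#' @param n_timepoints number of BOLD volumes per subject (default 200).
#' @param tr_seconds repetition time in seconds (default 3).
#' @param within_network_loading shared-signal loading in `[0, 1]`
#'   (default 0.6, i.e. within-network population r = 0.36).
#' @param ar1_coefficient AR(1) coefficient in `(-1, 1)` applied to both
#'   latent and unique innovations (default 0.3).
#' @param planted_edges data.frame with columns `roi_a`, `roi_b`,
#'   `delta_z`: edges whose population Fisher z is reduced by `delta_z`
#'   in `affected_group`. Default: [default_planted_edges()].
#' @param affected_group group label carrying the planted effect
#'   (default `"AD"`).
#' @param cdr_model list `(intercept, slope, noise_sd)` for
#'   CDR = intercept + slope * mean planted-edge z + noise, clipped to
#'   `[0, 3]`.
#' @param mmse_model same shape, for the MMSE-like score, clipped to
#'   `[0, 30]`.
#' @param cdr_realistic if `TRUE`, round CDR to the clinical half-point
#'   scale; default `FALSE` (continuous scores).
#' @param spike_fraction fraction of timepoints spiked in the nuisance
#'   traces (default 0.02).
#' @param seed integer RNG seed; all generation is a pure function of it.
#' @return an object of class `simulation_scenario` (a validated list).
#' @seealso [generate_cohort()], [generate_nuisance()]
#' @export
simulation_scenario <- function(n_per_group = c(HC = 31, MCI = 31, AD = 33),
                                n_timepoints = 200,
                                tr_seconds = 3,
                                within_network_loading = 0.6,
                                ar1_coefficient = 0.3,
                                planted_edges = default_planted_edges(),
                                affected_group = "AD",
                                cdr_model = list(intercept = 0.55, slope = -2.3,
                                                 noise_sd = 0.15),
                                mmse_model = list(intercept = 24.4, slope = 20,
                                                  noise_sd = 1.8),
                                cdr_realistic = FALSE,
                                spike_fraction = 0.02,
                                seed = 1L) {
  if (is.null(names(n_per_group)) || any(names(n_per_group) == ""))
    stopf("'n_per_group' must be a named vector of group sizes")
  if (n_timepoints < 10) stopf("'n_timepoints' must be >= 10")
  if (tr_seconds <= 0) stopf("'tr_seconds' must be positive")
  if (within_network_loading < 0 || within_network_loading > 1)
    stopf("'within_network_loading' must lie in [0, 1]")
  if (abs(ar1_coefficient) >= 1) stopf("'ar1_coefficient' must lie in (-1, 1)")
  if (!is.null(planted_edges)) {
    planted_edges <- as.data.frame(planted_edges)
    need <- c("roi_a", "roi_b", "delta_z")
    if (!all(need %in% names(planted_edges)))
      stopf("'planted_edges' needs columns roi_a, roi_b, delta_z")
    if (any(!is.finite(planted_edges$delta_z)))
      stopf("'delta_z' values must be finite")
  } else {
    planted_edges <- data.frame(roi_a = character(), roi_b = character(),
                                delta_z = numeric())
  }
  if (nrow(planted_edges) && !affected_group %in% names(n_per_group))
    stopf("'affected_group' (%s) is not a group in 'n_per_group'", affected_group)
  if (spike_fraction < 0 || spike_fraction > 0.5)
    stopf("'spike_fraction' must lie in [0, 0.5]")
  structure(
    list(n_per_group = n_per_group, n_timepoints = as.integer(n_timepoints),
         tr_seconds = tr_seconds,
         within_network_loading = within_network_loading,
         ar1_coefficient = ar1_coefficient,
         planted_edges = planted_edges, affected_group = affected_group,
         cdr_model = cdr_model, mmse_model = mmse_model,
         cdr_realistic = isTRUE(cdr_realistic),
         spike_fraction = spike_fraction, seed = as.integer(seed)),
    class = "simulation_scenario")
}

#' Default planted edge cluster
#'
#' Ten edges forming one contiguous cluster (connected when edges sharing
#' an ROI are neighbours): the six within-default-mode edges plus four
#' edges linking the default mode to sensorimotor and salience ROIs,
#' each reduced by `delta_z` Fisher-z units in the affected group.
#'
#' @param delta_z per-edge Fisher-z reduction (default 0.4).
#' @return data.frame with columns `roi_a`, `roi_b`, `delta_z`.
#' @export
default_planted_edges <- function(delta_z = 0.4) {
  dmn <- c("DefaultMode.MPFC", "DefaultMode.LP (L)", "DefaultMode.LP (R)",
           "DefaultMode.PCC")
  within <- t(utils::combn(dmn, 2))
  between <- rbind(
    c("DefaultMode.MPFC",   "SensoriMotor.Superior"),
    c("DefaultMode.PCC",    "SensoriMotor.Superior"),
    c("DefaultMode.PCC",    "Salience.ACC"),
    c("DefaultMode.LP (L)", "Salience.ACC"))
  edges <- rbind(within, between)
  data.frame(roi_a = edges[, 1], roi_b = edges[, 2], delta_z = delta_z,
             stringsAsFactors = FALSE)
}

# Population correlation matrix for one group under the scenario:
# block structure lambda^2 within network, planted edges shifted by -delta_z
# on the Fisher-z scale for the affected group.
population_correlation <- function(scenario, atlas, group) {
  lam2 <- scenario$within_network_loading^2
  net <- unname(scenario_network_of(atlas))
  S <- outer(net, net, "==") * lam2
  diag(S) <- 1
  pe <- scenario$planted_edges
  if (nrow(pe) && identical(group, scenario$affected_group)) {
    ia <- match(pe$roi_a, atlas$roi_labels)
    ib <- match(pe$roi_b, atlas$roi_labels)
    if (anyNA(ia) || anyNA(ib)) {
      bad <- c(pe$roi_a[is.na(ia)], pe$roi_b[is.na(ib)])[1]
      stopf("planted edge references unknown ROI: '%s'", bad)
    }
    r_new <- tanh(atanh(S[cbind(ia, ib)]) - pe$delta_z)
    if (any(abs(r_new) >= 1) || any(!is.finite(r_new)))
      stopf("planted delta_z produces |r| >= 1")
    S[cbind(ia, ib)] <- r_new
    S[cbind(ib, ia)] <- r_new
  }
  S
}

scenario_network_of <- function(atlas) atlas$network_of[atlas$roi_labels]

# Symmetric square root; errors if the planted configuration breaks
# positive definiteness.
sym_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) <= 1e-10)
    stopf("planted configuration makes the population correlation matrix non positive-definite (min eigenvalue %.3g)",
          min(e$values))
  e$vectors %*% (sqrt(e$values) * t(e$vectors))
}

# T x N matrix of independent unit-variance AR(1) series.
ar1_noise <- function(n_t, n_series, phi) {
  e <- matrix(stats::rnorm(n_t * n_series), n_t, n_series)
  if (phi == 0) return(e)
  x <- e
  x[1, ] <- e[1, ]
  s <- sqrt(1 - phi^2)
  for (t in 2:n_t) x[t, ] <- phi * x[t - 1, ] + s * e[t, ]
  x
}

#' Generate a synthetic multi-group cohort of ROI BOLD time series
#'
#' Each subject's ROI series are coloured AR(1) Gaussian processes whose
#' population correlation matrix has the scenario's block (within-network)
#' structure; subjects in the affected group have each planted edge's
#' population Fisher-z reduced by its `delta_z`, with every other edge's
#' population left unchanged. Columns are standardized (zero mean, unit
#' sd). CDR and the MMSE-like score are drawn from the scenario's linear
#' models applied to the subject's empirical mean planted-edge z.
#' Generation is a pure function of `scenario$seed`.
#'
#' @param scenario a [simulation_scenario()].
#' @param atlas a [network_atlas()]; default [default_atlas()].
#' @return list with elements `timeseries` (list of `roi_timeseries`,
#'   one per subject) and `design` (a [study_design()]).
#' @examples
#' sc <- simulation_scenario(n_per_group = c(HC = 4, AD = 4),
#'                           n_timepoints = 60, seed = 7)
#' cohort <- generate_cohort(sc)
#' cohort$design
#' @export
generate_cohort <- function(scenario, atlas = default_atlas()) {
  stopifnot(inherits(scenario, "simulation_scenario"),
            inherits(atlas, "network_atlas"))
  labels <- atlas$roi_labels
  n_roi <- length(labels)
  groups <- names(scenario$n_per_group)
  # one square root per group (population differs only for affected group)
  roots <- lapply(stats::setNames(groups, groups), function(g)
    sym_sqrt(population_correlation(scenario, atlas, g)))
  pe <- scenario$planted_edges
  pia <- match(pe$roi_a, labels); pib <- match(pe$roi_b, labels)

  with_seed(split_seed(scenario$seed, "cohort"), {
    ts_list <- list()
    subject_ids <- character(); group_of <- character()
    mean_pz <- numeric()
    for (g in groups) {
      for (k in seq_len(scenario$n_per_group[[g]])) {
        sid <- sprintf("%s%03d", g, k)
        eta <- ar1_noise(scenario$n_timepoints, n_roi, scenario$ar1_coefficient)
        x <- eta %*% roots[[g]]
        x <- scale(x)  # per-column standardization; correlations unaffected
        dimnames(x) <- list(NULL, labels)
        ts_list[[sid]] <- roi_timeseries(sid, x, labels, scenario$tr_seconds)
        subject_ids <- c(subject_ids, sid)
        group_of <- c(group_of, g)
        mean_pz <- c(mean_pz, if (nrow(pe)) {
          r <- stats::cor(x)
          mean(atanh(pmin(pmax(r[cbind(pia, pib)], -1 + 1e-7), 1 - 1e-7)))
        } else NA_real_)
      }
    }
    names(group_of) <- subject_ids
    cdr <- clinical_score(mean_pz, scenario$cdr_model, lo = 0, hi = 3)
    if (scenario$cdr_realistic) cdr <- round(cdr * 2) / 2
    mmse <- clinical_score(mean_pz, scenario$mmse_model, lo = 0, hi = 30)
    names(cdr) <- names(mmse) <- subject_ids
    design <- study_design(subject_ids, group_of, cdr = cdr, mmse = mmse,
                           seed = scenario$seed)
    list(timeseries = ts_list, design = design)
  })
}

clinical_score <- function(mean_z, model, lo, hi) {
  base <- ifelse(is.na(mean_z), 0, mean_z)
  raw <- model$intercept + model$slope * base +
    stats::rnorm(length(base), 0, model$noise_sd)
  pmin(pmax(raw, lo), hi)
}

#' ROI time-series object
#'
#' @param subject_id subject identifier.
#' @param data numeric matrix, timepoints x ROIs.
#' @param roi_labels column labels (atlas order).
#' @param tr_seconds repetition time.
#' @return object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(subject_id, data, roi_labels = colnames(data),
                           tr_seconds = 3) {
  data <- as.matrix(data)
  if (is.null(roi_labels)) stopf("'roi_labels' required")
  if (ncol(data) != length(roi_labels))
    stopf("column count (%d) does not match ROI label count (%d)",
          ncol(data), length(roi_labels))
  if (anyNA(data)) stopf("time series contains missing values")
  colnames(data) <- roi_labels
  structure(list(subject_id = subject_id, data = data,
                 roi_labels = roi_labels, tr_seconds = tr_seconds),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> subject %s: %d timepoints x %d ROIs (TR %gs)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Study design object
#'
#' Subject identifiers, diagnostic group labels and clinical scores for a
#' cohort, plus the seed the analysis derives its permutation streams from.
#'
#' @param subject_ids character vector, one entry per subject.
#' @param group_of named character vector mapping subject -> group.
#' @param cdr named numeric vector of global CDR scores (optional).
#' @param mmse named numeric vector of MMSE-like scores (optional).
#' @param seed integer master seed.
#' @return object of class `study_design`.
#' @export
study_design <- function(subject_ids, group_of, cdr = NULL, mmse = NULL,
                         seed = 1L) {
  if (anyDuplicated(subject_ids)) stopf("duplicate subject id")
  if (!all(subject_ids %in% names(group_of)))
    stopf("every subject needs a group label")
  structure(list(subject_ids = subject_ids,
                 group_of = group_of[subject_ids],
                 cdr = if (!is.null(cdr)) cdr[subject_ids],
                 mmse = if (!is.null(mmse)) mmse[subject_ids],
                 seed = as.integer(seed)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  tab <- table(x$group_of)
  cat(sprintf("<study_design> %d subjects: %s (seed %d)\n",
              length(x$subject_ids),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$seed))
  invisible(x)
}

#' Generate per-subject nuisance traces
#'
#' Framewise-displacement (mm) and global-signal traces with one value per
#' timepoint. A seeded fraction of timepoints (`scenario$spike_fraction`,
#' count `round(fraction * n_timepoints)`) is spiked: FD is set to 1.5 mm
#' (above the 0.9 mm scrubbing threshold) and the global signal is
#' displaced by 8 baseline standard deviations at the same timepoints.
#'
#' @param scenario a [simulation_scenario()].
#' @return named list (one element per subject id, matching
#'   [generate_cohort()] order) of data.frames with columns `fd`,
#'   `global_signal`.
#' @export
generate_nuisance <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  n_t <- scenario$n_timepoints
  n_spike <- round(scenario$spike_fraction * n_t)
  groups <- names(scenario$n_per_group)
  with_seed(split_seed(scenario$seed, "nuisance"), {
    out <- list()
    for (g in groups) {
      for (k in seq_len(scenario$n_per_group[[g]])) {
        sid <- sprintf("%s%03d", g, k)
        fd <- pmin(abs(stats::rnorm(n_t, 0.2, 0.05)), 0.8)
        gs <- stats::rnorm(n_t)
        if (n_spike > 0) {
          idx <- sample.int(n_t, n_spike)
          fd[idx] <- 1.5
          gs[idx] <- gs[idx] + 8 * sign(gs[idx] + (gs[idx] == 0))
        }
        out[[sid]] <- data.frame(fd = fd, global_signal = gs)
      }
    }
    out
  })
}
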