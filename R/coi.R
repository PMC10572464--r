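# Downstream analysis of clusters of interest (COIs): per-subject mean
# Fisher-z within a cluster, three-group ANOVA with pairwise t-tests, and
# within-group correlation with the global Clinical Dementia Rating.

coi_edges <- function(cluster) {
  e <- if (is.data.frame(cluster)) cluster else cluster$edges
  if (is.null(e) || !nrow(e)) stopf("cluster has no edges")
  if (!all(c("roi_a", "roi_b") %in% names(e)))
    stopf("cluster edges need 'roi_a' and 'roi_b' columns")
  e
}

#' Per-subject mean Fisher-z over a cluster's edges
#'
#' @param cluster a cluster from a fitted [tfce_test()] (or any
#'   data.frame with `roi_a`, `roi_b` columns of ROI labels).
#' @param z_matrices list of Fisher-z `connectivity_matrix` objects.
#' @return named numeric vector, one mean z per subject.
#' @export
coi_mean_z <- function(cluster, z_matrices) {
  e <- coi_edges(cluster)
  labs <- z_matrices[[1]]$roi_labels
  ia <- match(e$roi_a, labs); ib <- match(e$roi_b, labs)
  if (anyNA(ia) || anyNA(ib))
    stopf("cluster edge ROI not present in connectivity matrices: '%s'",
          c(e$roi_a[is.na(ia)], e$roi_b[is.na(ib)])[1])
  out <- vapply(z_matrices, function(m) mean(m$z[cbind(ia, ib)]), numeric(1))
  names(out) <- vapply(z_matrices, `[[`, "", "subject_id")
  out
}

#' Three-group ANOVA on cluster mean z with pairwise t-tests
#'
#' One-way fixed-effects ANOVA of per-subject cluster mean Fisher-z
#' across the design's groups, followed by pooled-variance t-tests for
#' every group pair. Pairwise p-values are reported unadjusted (matching
#' the presentation convention of per-pair tests); a Bonferroni-adjusted
#' column is included alongside for rigor.
#'
#' @param mean_z named per-subject mean z from [coi_mean_z()], or a
#'   cluster (in which case `z_matrices` must be supplied).
#' @param design a [study_design()].
#' @param z_matrices optional, used when `mean_z` is a cluster.
#' @param cluster_id label for the summary (default `"COI"`).
#' @return object of class `coi_summary`: list with `cluster_id`,
#'   `per_subject_mean_z`, `group_means`, `group_sd`, `anova_f`,
#'   `anova_p`, `df`, and `pairwise` (data.frame with `group_a`,
#'   `group_b`, `t`, `df`, `p`, `p_bonferroni`).
#' @export
coi_anova <- function(mean_z, design, z_matrices = NULL, cluster_id = "COI") {
  stopifnot(inherits(design, "study_design"))
  if (!is.numeric(mean_z)) {
    if (is.null(z_matrices)) stopf("'z_matrices' required when passing a cluster")
    mean_z <- coi_mean_z(mean_z, z_matrices)
  }
  mean_z <- mean_z[design$subject_ids]
  if (anyNA(mean_z)) stopf("mean z missing for some design subjects")
  grp <- factor(design$group_of[design$subject_ids])
  if (nlevels(grp) < 2 || any(table(grp) < 2))
    stopf("every group needs >= 2 subjects")
  if (all(tapply(mean_z, grp, stats::var) == 0) &&
      length(unique(tapply(mean_z, grp, mean))) == 1) {
    # identical degenerate groups: F = 0 by convention, p = 1
    fit_f <- 0; fit_p <- 1
  } else {
    if (all(tapply(mean_z, grp, stats::var) == 0))
      stopf("zero within-group variance; ANOVA undefined")
    aovfit <- stats::aov(mean_z ~ grp)
    tab <- summary(aovfit)[[1]]
    fit_f <- tab[["F value"]][1]
    fit_p <- tab[["Pr(>F)"]][1]
  }
  pairs <- utils::combn(levels(grp), 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    xa <- mean_z[grp == a]; xb <- mean_z[grp == b]
    if (stats::var(xa) == 0 && stats::var(xb) == 0 && mean(xa) == mean(xb)) {
      tt <- list(statistic = 0, parameter = length(xa) + length(xb) - 2, p.value = 1)
    } else {
      tt <- stats::t.test(xa, xb, var.equal = TRUE)
    }
    data.frame(group_a = a, group_b = b, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  pw$p_bonferroni <- pmin(pw$p * nrow(pw), 1)
  structure(list(cluster_id = cluster_id,
                 per_subject_mean_z = mean_z,
                 group_means = tapply(mean_z, grp, mean),
                 group_sd = tapply(mean_z, grp, stats::sd),
                 anova_f = fit_f, anova_p = fit_p,
                 df = c(nlevels(grp) - 1, length(mean_z) - nlevels(grp)),
                 pairwise = pw),
            class = "coi_summary")
}

#' @export
print.coi_summary <- function(x, ...) {
  cat(sprintf("COI summary (%s): F(%d, %d) = %.3f, p = %.4g\n",
              x$cluster_id, x$df[1], x$df[2], x$anova_f, x$anova_p))
  gm <- sprintf("%s = %.3f +/- %.3f", names(x$group_means), x$group_means, x$group_sd)
  cat("  group mean z:", paste(gm, collapse = ", "), "\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Within-group correlation of cluster mean z with CDR
#'
#' Pearson correlation between per-subject cluster mean Fisher-z and the
#' global Clinical Dementia Rating, within one diagnostic group, with the
#' two-sided p-value from the t-transform of R on n - 2 df. The reporting
#' flag implements the rule "report when p < 0.05 and |R| > 0.35
#' (equivalently R^2 > 0.1225)"; non-passing results are flagged, never
#' suppressed.
#'
#' @param cluster a cluster (or edge data.frame), or a named numeric
#'   vector of per-subject mean z.
#' @param z_matrices list of Fisher-z matrices (ignored when `cluster`
#'   is already a numeric vector).
#' @param design a [study_design()] carrying `cdr`.
#' @param group group label to restrict to.
#' @param cluster_id label for the result.
#' @return object of class `correlation_result`: list with `cluster_id`,
#'   `group`, `R`, `R2`, `p`, `n`, `passes_reporting_rule`.
#' @export
cdr_correlation <- function(cluster, z_matrices = NULL, design, group,
                            cluster_id = "COI") {
  stopifnot(inherits(design, "study_design"))
  if (is.null(design$cdr)) stopf("design has no CDR scores")
  mean_z <- if (is.numeric(cluster)) cluster else coi_mean_z(cluster, z_matrices)
  sel <- design$subject_ids[design$group_of[design$subject_ids] == group]
  sel <- intersect(sel, names(mean_z))
  if (length(sel) < 4) stopf("group '%s' needs >= 4 subjects with CDR", group)
  x <- mean_z[sel]; y <- design$cdr[sel]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero variance in mean z or CDR within group '%s'; correlation undefined", group)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  R <- unname(ct$estimate)
  structure(list(cluster_id = cluster_id, group = group,
                 R = R, R2 = R^2, p = ct$p.value, n = length(sel),
                 passes_reporting_rule = reporting_rule(R, ct$p.value)),
            class = "correlation_result")
}

#' The CDR-correlation reporting rule
#'
#' A pure function of (R, p): passes iff `p < 0.05` and `|R| > 0.35`.
#'
#' @param R Pearson correlation.
#' @param p two-sided p-value.
#' @return logical.
#' @export
reporting_rule <- function(R, p) p < 0.05 & abs(R) > 0.35

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("CDR correlation (%s, %s): R = %.3f (R2 = %.3f), p = %.4g, n = %d%s\n",
              x$cluster_id, x$group, x$R, x$R2, x$p, x$n,
              if (x$passes_reporting_rule) " [passes reporting rule]"
              else " [below reporting rule]"))
  invisible(x)
}
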