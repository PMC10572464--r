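# Edgewise group-contrast statistics on Fisher-z connectivity matrices.
# Edges are the strict upper triangle (i < j), mirrored for storage; the
# diagonal never enters statistics.

#' Stack Fisher-z matrices into a subjects x edges matrix
#'
#' @param z_matrices list of `connectivity_matrix` objects (with `z`),
#'   all sharing the same ROI ordering.
#' @return list with `Z` (subjects x edges matrix, rownames = subject
#'   ids), `pairs` (edge index matrix, columns `row`/`col`, i < j) and
#'   `roi_labels`.
#' @export
stack_z <- function(z_matrices) {
  stopifnot(length(z_matrices) >= 1)
  labs <- z_matrices[[1]]$roi_labels
  for (m in z_matrices) {
    stopifnot(inherits(m, "connectivity_matrix"))
    if (is.null(m$z)) stopf("matrix for subject %s lacks Fisher z (run fisher_z)", m$subject_id)
    if (!identical(m$roi_labels, labs))
      stopf("ROI ordering differs for subject %s", m$subject_id)
  }
  pairs <- upper_tri_pairs(length(labs))
  Z <- t(vapply(z_matrices, function(m) m$z[pairs], numeric(nrow(pairs))))
  rownames(Z) <- vapply(z_matrices, `[[`, "", "subject_id")
  list(Z = Z, pairs = pairs, roi_labels = labs)
}

# Pooled-variance (or Welch) two-sample t per column of Z.
# Zero pooled variance at a column gives t = 0.
col_t_stats <- function(Z, in_a, in_b, welch = FALSE) {
  na <- sum(in_a); nb <- sum(in_b)
  ma <- colMeans(Z[in_a, , drop = FALSE])
  mb <- colMeans(Z[in_b, , drop = FALSE])
  va <- colSums(sweep(Z[in_a, , drop = FALSE], 2, ma)^2) / (na - 1)
  vb <- colSums(sweep(Z[in_b, , drop = FALSE], 2, mb)^2) / (nb - 1)
  if (welch) {
    se2 <- va / na + vb / nb
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
  }
  t <- ifelse(se2 == 0, 0, (ma - mb) / sqrt(se2))
  attr(t, "degenerate") <- se2 == 0
  t
}

# One-way fixed-effects F per column of Z across the groups in `g`.
col_f_stats <- function(Z, g) {
  g <- factor(g)
  n <- nrow(Z)
  k <- nlevels(g)
  grand <- colMeans(Z)
  ssb <- 0; ssw <- 0
  for (lev in levels(g)) {
    sel <- g == lev
    m <- colMeans(Z[sel, , drop = FALSE])
    ssb <- ssb + sum(sel) * (m - grand)^2
    ssw <- ssw + colSums(sweep(Z[sel, , drop = FALSE], 2, m)^2)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  ifelse(msw == 0, 0, msb / msw)
}

edge_vec_to_matrix <- function(v, pairs, n, labels = NULL) {
  m <- matrix(0, n, n)
  m[pairs] <- v
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

#' Edgewise two-sample t map
#'
#' Per edge, the pooled-variance two-sample t of `group_a` minus
#' `group_b` on Fisher-z values (positive t means `group_a` > `group_b`),
#' df = n_a + n_b - 2. Edges with zero pooled variance get t = 0 with a
#' warning.
#'
#' @param z_matrices list of Fisher-z `connectivity_matrix` objects.
#' @param design a [study_design()].
#' @param group_a,group_b group labels to contrast.
#' @param welch use the Welch (unequal-variance) statistic instead of the
#'   classical pooled GLM contrast. Default `FALSE`.
#' @return object of class `edge_stat_map`: list with `stat` (N x N
#'   symmetric, zero diagonal), `stat_kind = "t"`, `df`, `contrast`,
#'   `roi_labels`.
#' @export
two_sample_t_map <- function(z_matrices, design, group_a, group_b,
                             welch = FALSE) {
  stopifnot(inherits(design, "study_design"))
  st <- stack_z(z_matrices)
  grp <- design$group_of[rownames(st$Z)]
  in_a <- grp == group_a
  in_b <- grp == group_b
  if (sum(in_a, na.rm = TRUE) < 2 || sum(in_b, na.rm = TRUE) < 2)
    stopf("each contrast group needs >= 2 subjects (%s: %d, %s: %d)",
          group_a, sum(in_a, na.rm = TRUE), group_b, sum(in_b, na.rm = TRUE))
  in_a[is.na(in_a)] <- FALSE; in_b[is.na(in_b)] <- FALSE
  t_vals <- col_t_stats(st$Z, in_a, in_b, welch = welch)
  n <- length(st$roi_labels)
  if (any(attr(t_vals, "degenerate")))
    warnf("%d edge(s) with zero pooled variance set to t = 0",
          sum(attr(t_vals, "degenerate")))
  attr(t_vals, "degenerate") <- NULL
  structure(list(stat = edge_vec_to_matrix(t_vals, st$pairs, n, st$roi_labels),
                 stat_kind = "t",
                 df = sum(in_a) + sum(in_b) - 2L,
                 contrast = paste0(group_a, ">", group_b),
                 roi_labels = st$roi_labels),
            class = "edge_stat_map")
}

#' Edgewise one-way ANOVA F map
#'
#' Per edge, the one-way fixed-effects F across all groups in the design
#' (three diagnostic groups in the canonical analysis),
#' df = (k - 1, n - k).
#'
#' @inheritParams two_sample_t_map
#' @return an `edge_stat_map` with `stat_kind = "F"`.
#' @export
anova_f_map <- function(z_matrices, design) {
  stopifnot(inherits(design, "study_design"))
  st <- stack_z(z_matrices)
  grp <- design$group_of[rownames(st$Z)]
  tab <- table(grp)
  if (any(tab < 2)) stopf("every group needs >= 2 subjects")
  f_vals <- col_f_stats(st$Z, grp)
  n <- length(st$roi_labels)
  structure(list(stat = edge_vec_to_matrix(f_vals, st$pairs, n, st$roi_labels),
                 stat_kind = "F",
                 df = c(length(tab) - 1L, nrow(st$Z) - length(tab)),
                 contrast = paste(names(tab), collapse = "~"),
                 roi_labels = st$roi_labels),
            class = "edge_stat_map")
}

#' @export
print.edge_stat_map <- function(x, ...) {
  cat(sprintf("<edge_stat_map> %s map, contrast %s, df %s; |stat| max %.3f\n",
              x$stat_kind, x$contrast, paste(x$df, collapse = ","),
              max(abs(x$stat))))
  invisible(x)
}
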