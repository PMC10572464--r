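# Permutation inference for TFCE and NBS on ROI-to-ROI connectivity.

#' TFCE group comparison with permutation inference
#'
#' The central fitting function. Computes the edgewise two-sample t map
#' for the requested contrast on Fisher-z connectivity, enhances it with
#' threshold-free cluster enhancement (both tails), and builds the null
#' distribution by complete re-randomization of group labels among the
#' contrast's subjects (identity permutation excluded). Each permutation
#' contributes its maximum TFCE score (peak) and maximum cluster mass.
#'
#' Cluster formation on the observed map uses, by default, connected
#' components of edges whose |TFCE| exceeds the 95th percentile of the
#' pooled null edgewise |TFCE| distribution (`cluster_rule = "null_q95"`,
#' a deterministic, documented rule); `"nonzero"` instead takes components
#' of all nonzero-TFCE edges. Cluster mass is the sum of the edgewise
#' |t| over the cluster's edges (`mass_type = "stat"`), or of |TFCE|
#' scores (`"tfce"`).
#'
#' P-values use the add-one estimator
#' `(1 + #(null >= observed)) / (1 + n_permutations)`, so the smallest
#' attainable p is `1/(n_permutations + 1)`:
#' `peak_p_fwe` compares a cluster's peak TFCE with the null peaks
#' (family-wise error control via the maximum statistic) and
#' `p_uncorrected` compares its mass with the null maximum masses.
#'
#' @param z_matrices list of Fisher-z `connectivity_matrix` objects.
#' @param design a [study_design()].
#' @param contrast character vector of two group labels
#'   `c(group_a, group_b)`; positive statistics mean group_a > group_b.
#' @param params a [tfce_params()].
#' @param n_permutations number of label permutations (>= 100;
#'   default 1000).
#' @param seed integer seed for the permutation stream; default derived
#'   from `design$seed` and the contrast via [split_seed()].
#' @param roi_order hierarchical ROI order from [sort_rois()]; computed
#'   from the contrast subjects' matrices when `NULL`.
#' @param cluster_rule `"null_q95"` (default) or `"nonzero"`, see above.
#' @param mass_type `"stat"` (default) or `"tfce"`, see above.
#' @param atlas optional [network_atlas()] used to annotate clusters with
#'   the networks they involve.
#' @param welch use Welch t statistics instead of pooled-variance.
#' @return an object of class `tfce_test`; see Details. Fields include
#'   `tfce_map` (signed, original ROI order), `stat_map` (the observed
#'   `edge_stat_map`), `roi_order`, `clusters` (list; each with `edges`,
#'   `mass`, `p_uncorrected`, `peak_tfce`, `peak_p_fwe`, `sign`,
#'   `networks_involved`), `null_peaks`, `null_masses`,
#'   `cluster_threshold`, `global_peak`, `global_peak_p_fwe`,
#'   `n_permutations`, `seed`, `params`, `contrast`.
#' @seealso [nbs()], [extract_report()], [coi_mean_z()]
#' @examples
#' \donttest{
#' sc <- simulation_scenario(n_per_group = c(HC = 8, AD = 8),
#'                           n_timepoints = 80, seed = 3)
#' ch <- generate_cohort(sc)
#' zs <- lapply(ch$timeseries, connectivity)
#' fit <- tfce_test(zs, ch$design, c("HC", "AD"), n_permutations = 100)
#' fit
#' }
#' @export
tfce_test <- function(z_matrices, design, contrast = c("HC", "AD"),
                      params = tfce_params(), n_permutations = 1000L,
                      seed = NULL, roi_order = NULL,
                      cluster_rule = c("null_q95", "nonzero"),
                      mass_type = c("stat", "tfce"),
                      atlas = NULL, welch = FALSE) {
  stopifnot(inherits(design, "study_design"), length(contrast) == 2)
  cluster_rule <- match.arg(cluster_rule)
  mass_type <- match.arg(mass_type)
  if (n_permutations < 100) stopf("'n_permutations' must be >= 100")
  if (is.null(seed))
    seed <- split_seed(design$seed, paste0("perm:", contrast[1], ">", contrast[2]))

  st <- stack_z(z_matrices)
  grp <- design$group_of[rownames(st$Z)]
  keep <- grp %in% contrast
  Z <- st$Z[keep, , drop = FALSE]
  grp <- grp[keep]
  in_a0 <- grp == contrast[1]
  if (sum(in_a0) < 2 || sum(!in_a0) < 2)
    stopf("each contrast group needs >= 2 subjects")
  n <- length(st$roi_labels)
  if (is.null(roi_order))
    roi_order <- sort_rois(z_matrices[match(rownames(Z),
      vapply(z_matrices, `[[`, "", "subject_id"))])
  pairs_sorted <- upper_tri_pairs(n)

  to_sorted <- function(v) {
    m <- edge_vec_to_matrix(v, st$pairs, n)
    m[roi_order, roi_order]
  }

  t_obs_sorted <- to_sorted(strip_attr(col_t_stats(Z, in_a0, !in_a0, welch)))
  tfce_obs_sorted <- tfce_core(t_obs_sorted, params)

  B <- as.integer(n_permutations)
  m_ut <- nrow(pairs_sorted)
  tfce_null_ut <- matrix(0, B, m_ut)
  stat_null_ut <- matrix(0, B, m_ut)
  null_peaks <- numeric(B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      in_a <- draw_permutation(in_a0)
      ts <- to_sorted(strip_attr(col_t_stats(Z, in_a, !in_a, welch)))
      tf <- tfce_core(ts, params)
      tfce_null_ut[b, ] <- tf[pairs_sorted]
      stat_null_ut[b, ] <- abs(ts[pairs_sorted])
      null_peaks[b] <- max(abs(tf))
    }
  })

  thr <- if (cluster_rule == "null_q95")
    stats::quantile(abs(tfce_null_ut), 0.95, names = FALSE) else 0

  cl_obs <- extract_clusters(tfce_obs_sorted, abs(t_obs_sorted), thr,
                             params$neighborhood, mass_type)
  null_masses <- vapply(seq_len(B), function(b) {
    tf <- edge_vec_to_matrix(tfce_null_ut[b, ], pairs_sorted, n)
    sm <- edge_vec_to_matrix(stat_null_ut[b, ], pairs_sorted, n)
    cl <- extract_clusters(tf, sm, thr, params$neighborhood, mass_type)
    if (length(cl)) max(vapply(cl, `[[`, 0, "mass")) else 0
  }, numeric(1))

  labels_sorted <- st$roi_labels[roi_order]
  clusters <- lapply(cl_obs, function(cl) {
    e_lab <- cbind(labels_sorted[cl$edges[, 1]], labels_sorted[cl$edges[, 2]])
    e_lab <- t(apply(e_lab, 1, sort))  # canonical unordered pairs
    nets <- unique(parse_roi_label(as.vector(e_lab))$network)
    if (!is.null(atlas)) {
      unknown <- setdiff(as.vector(e_lab), atlas$roi_labels)
      if (length(unknown)) stopf("cluster edge label not in atlas: '%s'", unknown[1])
    }
    list(edges = data.frame(roi_a = e_lab[, 1], roi_b = e_lab[, 2],
                            stat = cl$edge_stat, stringsAsFactors = FALSE),
         mass = cl$mass,
         p_uncorrected = (1 + sum(null_masses >= cl$mass)) / (1 + B),
         peak_tfce = cl$peak,
         peak_p_fwe = (1 + sum(null_peaks >= cl$peak)) / (1 + B),
         sign = cl$sign,
         networks_involved = sort(nets))
  })
  # order clusters by mass, largest first
  if (length(clusters))
    clusters <- clusters[order(-vapply(clusters, `[[`, 0, "mass"))]

  # un-sort maps back to original ROI order
  unsort <- function(ms) {
    m <- matrix(0, n, n)
    m[roi_order, roi_order] <- ms
    dimnames(m) <- list(st$roi_labels, st$roi_labels)
    m
  }
  global_peak <- max(abs(tfce_obs_sorted))
  structure(
    list(tfce_map = unsort(tfce_obs_sorted),
         stat_map = structure(list(stat = unsort(t_obs_sorted), stat_kind = "t",
                                   df = nrow(Z) - 2L,
                                   contrast = paste0(contrast[1], ">", contrast[2]),
                                   roi_labels = st$roi_labels),
                              class = "edge_stat_map"),
         roi_order = roi_order, clusters = clusters,
         null_peaks = null_peaks, null_masses = null_masses,
         cluster_threshold = thr, cluster_rule = cluster_rule,
         mass_type = mass_type,
         global_peak = global_peak,
         global_peak_p_fwe = (1 + sum(null_peaks >= global_peak)) / (1 + B),
         n_permutations = B, seed = seed, params = params,
         contrast = paste0(contrast[1], ">", contrast[2]),
         n_subjects = nrow(Z)),
    class = "tfce_test")
}

strip_attr <- function(x) { attributes(x) <- NULL; x }

# Shuffle a two-group indicator, excluding the identity assignment.
draw_permutation <- function(in_a0) {
  for (i in 1:10000) {
    p <- sample(in_a0)
    if (!identical(p, in_a0)) return(p)
  }
  stopf("contrast groups too small for any distinct permutation")
}

# Clusters of a signed TFCE map (sorted space): per sign, components of
# entries beyond `thr` under the given neighbourhood. Mirror-image
# components (the two symmetric halves) are de-duplicated by their edge
# set. Returns list of (edges [i<j sorted-space], edge_stat, mass, peak,
# sign).
extract_clusters <- function(tfce_sorted, absstat_sorted, thr, neighborhood,
                             mass_type) {
  out <- list()
  seen <- character()
  for (sgn in c(1, -1)) {
    mask <- (sgn * tfce_sorted) > thr
    if (!any(mask)) next
    lab <- if (neighborhood == "matrix_image_4") cpp_label_image4(mask)
           else cpp_label_edge_graph(mask)
    for (k in seq_len(max(lab))) {
      cells <- which(lab == k, arr.ind = TRUE)
      e <- unique(cbind(pmin(cells[, 1], cells[, 2]),
                        pmax(cells[, 1], cells[, 2])))
      e <- e[e[, 1] != e[, 2], , drop = FALSE]
      if (!nrow(e)) next
      e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
      key <- paste(e[, 1], e[, 2], sep = "-", collapse = ";")
      if (key %in% seen) next
      seen <- c(seen, key)
      stat_vals <- absstat_sorted[e]
      tfce_vals <- abs(tfce_sorted)[e]
      out[[length(out) + 1]] <- list(
        edges = e, edge_stat = stat_vals,
        mass = if (mass_type == "stat") sum(stat_vals) else sum(tfce_vals),
        peak = max(tfce_vals),
        sign = if (sgn > 0) "positive" else "negative")
    }
  }
  out
}

#' @export
print.tfce_test <- function(x, ...) {
  cat(sprintf("TFCE permutation test: %s (%d subjects, %d permutations)\n",
              x$contrast, x$n_subjects, x$n_permutations))
  cat(sprintf("  neighbourhood %s, E = %g, H = %g, %d height steps\n",
              x$params$neighborhood, x$params$E, x$params$H, x$params$n_steps))
  cat(sprintf("  global peak TFCE %.3f, peak-level FWE p = %.4g\n",
              x$global_peak, x$global_peak_p_fwe))
  if (!length(x$clusters)) {
    cat("  no clusters above the cluster-forming threshold\n")
  } else {
    cat(sprintf("  %d cluster(s) (threshold %.3f):\n", length(x$clusters),
                x$cluster_threshold))
    print(summary(x), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.tfce_test <- function(object, ...) {
  cl <- object$clusters
  data.frame(
    cluster = seq_along(cl),
    n_edges = vapply(cl, function(c) nrow(c$edges), 0L),
    mass = vapply(cl, `[[`, 0, "mass"),
    p_uncorrected = vapply(cl, `[[`, 0, "p_uncorrected"),
    peak_tfce = vapply(cl, `[[`, 0, "peak_tfce"),
    peak_p_fwe = vapply(cl, `[[`, 0, "peak_p_fwe"),
    sign = vapply(cl, `[[`, "", "sign"),
    networks = vapply(cl, function(c) paste(c$networks_involved, collapse = ","), ""),
    stringsAsFactors = FALSE)
}

#' Plot a fitted TFCE comparison
#'
#' Displays the signed TFCE map (hierarchically sorted ROI order) as an
#' image, with the cluster-forming threshold applied as a contour of
#' cluster membership.
#'
#' @param x a `tfce_test` object.
#' @param ... passed to [graphics::image()].
#' @export
plot.tfce_test <- function(x, ...) {
  ord <- x$roi_order
  m <- x$tfce_map[ord, ord]
  lim <- max(abs(m), 1e-12)
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), t(m[rev(seq_len(nrow(m))), ]),
                  zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "ROI (sorted)", ylab = "ROI (sorted)",
                  main = sprintf("TFCE map: %s", x$contrast), ...)
  invisible(x)
}

#' Network-based statistic (NBS) comparator
#'
#' The fixed-threshold alternative to TFCE: edges with |t| above
#' `edge_threshold` (per tail) are grouped into connected components
#' (edges adjacent iff they share an ROI); component size (edge count)
#' and mass (sum of |t|) are computed, and the family-wise p-value of
#' each component compares its size with the permutation null of maximum
#' component sizes.
#'
#' @inheritParams tfce_test
#' @param edge_threshold positive t threshold defining suprathreshold
#'   edges (default 3).
#' @return object of class `nbs_test` with `components` (list of `edges`,
#'   `size`, `mass`, `p_fwe`, `sign`), `null_max_size`, `threshold`,
#'   `n_permutations`, `seed`, `contrast`.
#' @export
nbs <- function(z_matrices, design, contrast = c("HC", "AD"),
                edge_threshold = 3, n_permutations = 1000L, seed = NULL,
                welch = FALSE) {
  stopifnot(inherits(design, "study_design"), length(contrast) == 2)
  if (edge_threshold <= 0) stopf("'edge_threshold' must be positive")
  if (is.null(seed))
    seed <- split_seed(design$seed, paste0("nbs:", contrast[1], ">", contrast[2]))
  st <- stack_z(z_matrices)
  grp <- design$group_of[rownames(st$Z)]
  keep <- grp %in% contrast
  Z <- st$Z[keep, , drop = FALSE]
  grp <- grp[keep]
  in_a0 <- grp == contrast[1]
  if (sum(in_a0) < 2 || sum(!in_a0) < 2)
    stopf("each contrast group needs >= 2 subjects")
  n <- length(st$roi_labels)

  t_obs <- edge_vec_to_matrix(strip_attr(col_t_stats(Z, in_a0, !in_a0, welch)),
                              st$pairs, n, st$roi_labels)
  comps <- nbs_components(t_obs, edge_threshold)

  B <- as.integer(n_permutations)
  null_max_size <- numeric(B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      in_a <- draw_permutation(in_a0)
      tp <- edge_vec_to_matrix(strip_attr(col_t_stats(Z, in_a, !in_a, welch)),
                               st$pairs, n)
      cp <- nbs_components(tp, edge_threshold)
      null_max_size[b] <- if (length(cp)) max(vapply(cp, `[[`, 0L, "size")) else 0
    }
  })
  components <- lapply(comps, function(cp) {
    cp$p_fwe <- (1 + sum(null_max_size >= cp$size)) / (1 + B)
    cp$edges <- data.frame(roi_a = st$roi_labels[cp$edges[, 1]],
                           roi_b = st$roi_labels[cp$edges[, 2]],
                           stat = cp$edge_stat, stringsAsFactors = FALSE)
    cp$edge_stat <- NULL
    cp
  })
  if (length(components))
    components <- components[order(-vapply(components, `[[`, 0, "mass"))]
  structure(list(components = components, null_max_size = null_max_size,
                 threshold = edge_threshold, n_permutations = B, seed = seed,
                 contrast = paste0(contrast[1], ">", contrast[2])),
            class = "nbs_test")
}

# Suprathreshold components of a signed t matrix, per tail.
nbs_components <- function(t_mat, threshold) {
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- (sgn * t_mat) > threshold
    if (!any(mask)) next
    lab <- cpp_label_edge_graph(mask)
    for (k in seq_len(max(lab))) {
      cells <- which(lab == k & upper.tri(lab), arr.ind = TRUE)
      if (!nrow(cells)) next
      out[[length(out) + 1]] <- list(
        edges = cells, edge_stat = abs(t_mat)[cells],
        size = nrow(cells), mass = sum(abs(t_mat)[cells]),
        sign = if (sgn > 0) "positive" else "negative")
    }
  }
  out
}

#' @export
print.nbs_test <- function(x, ...) {
  cat(sprintf("NBS permutation test: %s (threshold |t| > %g, %d permutations)\n",
              x$contrast, x$threshold, x$n_permutations))
  if (!length(x$components)) {
    cat("  no suprathreshold components\n")
  } else {
    for (i in seq_along(x$components)) {
      cp <- x$components[[i]]
      cat(sprintf("  component %d (%s): %d edges, mass %.2f, FWE p = %.4g\n",
                  i, cp$sign, cp$size, cp$mass, cp$p_fwe))
    }
  }
  invisible(x)
}

#' Edge-list report of a fitted TFCE comparison
#'
#' One row per cluster edge, labelled `Network.ROI (hemisphere)`, ordered
#' within cluster by |t| descending, with the cluster's mass and both
#' p-values repeated on each row (the uncorrected cluster-level p is the
#' headline figure; the peak-level FWE-corrected p is reported alongside).
#'
#' @param result a `tfce_test`.
#' @param atlas a [network_atlas()] used to validate edge labels.
#' @return data.frame with columns `cluster`, `sign`, `mass`,
#'   `p_uncorrected`, `peak_p_fwe`, `roi_a`, `roi_b`, `stat`.
#' @export
extract_report <- function(result, atlas = default_atlas()) {
  stopifnot(inherits(result, "tfce_test"))
  rows <- list()
  for (i in seq_along(result$clusters)) {
    cl <- result$clusters[[i]]
    e <- cl$edges[order(-abs(cl$edges$stat)), , drop = FALSE]
    if (!is.null(atlas)) {
      unknown <- setdiff(c(e$roi_a, e$roi_b), atlas$roi_labels)
      if (length(unknown)) stopf("edge label not in atlas: '%s'", unknown[1])
    }
    rows[[i]] <- data.frame(cluster = i, sign = cl$sign, mass = cl$mass,
                            p_uncorrected = cl$p_uncorrected,
                            peak_p_fwe = cl$peak_p_fwe,
                            roi_a = e$roi_a, roi_b = e$roi_b, stat = e$stat,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(cluster = integer(), sign = character(), mass = numeric(),
                      p_uncorrected = numeric(), peak_p_fwe = numeric(),
                      roi_a = character(), roi_b = character(), stat = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read an edge-list report as tab-delimited text
#'
#' `read_report(write_report(x, f))` recovers the data.frame exactly
#' (numbers serialized at full precision).
#'
#' @param report data.frame from [extract_report()].
#' @param path output path.
#' @return `path` invisibly (writer); the data.frame (reader).
#' @export
write_report <- function(report, path) {
  fmt <- report
  for (cc in names(fmt)) if (is.numeric(fmt[[cc]]) && !is.integer(fmt[[cc]]))
    fmt[[cc]] <- sprintf("%.17g", fmt[[cc]])
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (cc in c("mass", "p_uncorrected", "peak_p_fwe", "stat"))
    if (cc %in% names(out)) out[[cc]] <- as.numeric(out[[cc]])
  if ("cluster" %in% names(out)) out$cluster <- as.integer(out$cluster)
  out
}
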