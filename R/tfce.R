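#' TFCE parameters
#'
#' Configuration for threshold-free cluster enhancement of an edgewise
#' statistic map. The enhancement of edge (i, j) is the discretized
#' integral over heights h from `h0` to the tail maximum of
#' `e(h)^E * h^H dh`, where `e(h)` is the extent of the suprathreshold
#' component containing the edge at level h.
#'
#' @param E extension exponent (default 0.5, the canonical published
#'   default).
#' @param H height exponent (default 2.0).
#' @param n_steps number of height levels for the midpoint discretization
#'   (default 100; must be >= 10).
#' @param h0 starting height (default 0).
#' @param two_sided enhance the positive and negative tails separately and
#'   return a signed map (default `TRUE`).
#' @param neighborhood component-forming rule: `"matrix_image_4"` (the
#'   ROI-sorted N x N matrix treated as a 2-D image, 4-connectivity, both
#'   symmetric halves as one image — this is why the hierarchical ROI
#'   sorting matters) or `"edge_graph"` (suprathreshold edges adjacent
#'   iff they share an ROI; sorting-invariant).
#' @return object of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2.0, n_steps = 100L, h0 = 0,
                        two_sided = TRUE,
                        neighborhood = c("matrix_image_4", "edge_graph")) {
  neighborhood <- match.arg(neighborhood)
  if (E < 0 || H < 0) stopf("'E' and 'H' must be non-negative")
  if (n_steps < 10) stopf("'n_steps' must be >= 10")
  if (h0 < 0) stopf("'h0' must be >= 0")
  structure(list(E = E, H = H, n_steps = as.integer(n_steps), h0 = h0,
                 two_sided = isTRUE(two_sided), neighborhood = neighborhood),
            class = "tfce_params")
}

neighbourhood_code <- function(neighborhood) {
  match(neighborhood, c("matrix_image_4", "edge_graph")) - 1L
}

#' Hierarchical ROI sorting
#'
#' Orders ROIs by average-linkage agglomerative clustering on the distance
#' `1 - |mean z|` across subjects, returning the dendrogram leaf order.
#' Strongly connected ROI groups become contiguous, so that compact
#' clusters form connected regions when the sorted matrix is treated as a
#' 2-D image.
#'
#' @param z_matrices list of Fisher-z `connectivity_matrix` objects.
#' @return integer permutation of ROI indices (the leaf order).
#' @export
sort_rois <- function(z_matrices) {
  st <- stack_z(z_matrices)
  n <- length(st$roi_labels)
  if (n < 3) return(seq_len(n))
  mean_z <- edge_vec_to_matrix(colMeans(st$Z), st$pairs, n)
  d <- 1 - abs(mean_z)
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  hc$order
}

#' Threshold-free cluster enhancement of an edgewise statistic map
#'
#' Enhances each edge's statistic by integrating component extent and
#' height over all thresholds (midpoint rule over `n_steps` levels), so
#' that no single cluster-forming threshold has to be chosen. With
#' `two_sided = TRUE` the positive and negative tails are enhanced
#' separately and negative-tail scores are returned with negative sign.
#'
#' @param stat_map an `edge_stat_map` (or a plain symmetric matrix with
#'   zero diagonal).
#' @param roi_order integer permutation from [sort_rois()]; used only by
#'   the `matrix_image_4` neighbourhood (components are formed on the
#'   sorted image). Default: identity.
#' @param params a [tfce_params()].
#' @return symmetric numeric matrix of signed TFCE scores, in the input
#'   ROI order.
#' @export
tfce_enhance <- function(stat_map, roi_order = NULL, params = tfce_params()) {
  stat <- if (inherits(stat_map, "edge_stat_map")) stat_map$stat else stat_map
  stopifnot(is.matrix(stat), nrow(stat) == ncol(stat),
            inherits(params, "tfce_params"))
  if (max(abs(stat - t(stat))) > 1e-8) stopf("stat map must be symmetric")
  n <- nrow(stat)
  if (is.null(roi_order)) roi_order <- seq_len(n)
  sorted <- stat[roi_order, roi_order]
  enh_sorted <- tfce_core(sorted, params)
  out <- matrix(0, n, n)
  out[roi_order, roi_order] <- enh_sorted
  dimnames(out) <- dimnames(stat)
  out
}

# Enhancement in (already sorted) matrix space; returns signed map.
tfce_core <- function(sorted_stat, params) {
  code <- neighbourhood_code(params$neighborhood)
  pos <- pmax(sorted_stat, 0)
  enh <- cpp_tfce_tail(pos, params$E, params$H, params$n_steps, params$h0, code)
  if (params$two_sided) {
    neg <- pmax(-sorted_stat, 0)
    enh <- enh - cpp_tfce_tail(neg, params$E, params$H, params$n_steps,
                               params$h0, code)
  }
  enh
}
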