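# Fixture builders shared across tests. Everything is generated in code.

# connectivity_matrix built directly from a given Fisher-z matrix
make_conn <- function(z, subject_id, roi_labels = NULL) {
  n <- nrow(z)
  if (is.null(roi_labels)) roi_labels <- paste0("Net.R", seq_len(n))
  diag(z) <- 0
  dimnames(z) <- list(roi_labels, roi_labels)
  r <- tanh(z); diag(r) <- 1
  structure(list(subject_id = subject_id, r = r, z = z,
                 roi_labels = roi_labels, n_timepoints_used = NA_integer_),
            class = "connectivity_matrix")
}

# subjects whose z matrices are constant at given per-subject values
constant_z_cohort <- function(values_by_group, n_roi = 4) {
  zs <- list(); ids <- character(); grp <- character()
  for (g in names(values_by_group)) {
    for (k in seq_along(values_by_group[[g]])) {
      id <- sprintf("%s%02d", g, k)
      z <- matrix(values_by_group[[g]][k], n_roi, n_roi)
      zs[[id]] <- make_conn(z, id)
      ids <- c(ids, id); grp <- c(grp, g)
    }
  }
  names(grp) <- ids
  list(z_matrices = zs, design = study_design(ids, grp, seed = 1L))
}

# small simulated cohort (two groups, planted default cluster optional)
sim_cohort <- function(n_hc = 10, n_ad = 10, n_t = 100, seed = 1,
                       planted = TRUE, delta_z = 0.4, loading = 0.6) {
  sc <- simulation_scenario(
    n_per_group = c(HC = n_hc, AD = n_ad), n_timepoints = n_t,
    within_network_loading = loading,
    planted_edges = if (planted) default_planted_edges(delta_z) else NULL,
    affected_group = "AD", seed = seed)
  ch <- generate_cohort(sc)
  ch$z_matrices <- lapply(ch$timeseries, connectivity)
  ch
}

planted_edge_keys <- function(edges = default_planted_edges()) {
  paste(pmin(edges$roi_a, edges$roi_b), pmax(edges$roi_a, edges$roi_b),
        sep = " ~ ")
}

cluster_edge_keys <- function(cluster) {
  e <- cluster$edges
  paste(pmin(e$roi_a, e$roi_b), pmax(e$roi_a, e$roi_b), sep = " ~ ")
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
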