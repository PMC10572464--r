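test_that("a dominant observed peak attains the floor p-value", {
  # perfectly separated groups: every non-identity relabelling weakens the
  # contrast, so the observed peak beats every null peak
  set.seed(71)
  vals <- list(A = 0.5 + rnorm(8, sd = 0.02), B = -0.5 + rnorm(8, sd = 0.02))
  co <- constant_z_cohort(vals, n_roi = 6)
  fit <- tfce_test(co$z_matrices, co$design, c("A", "B"),
                   n_permutations = 100, seed = 1)
  expect_equal(fit$global_peak_p_fwe, 1 / 101)
  expect_gt(length(fit$clusters), 0)
  expect_equal(fit$clusters[[1]]$peak_p_fwe, 1 / 101)
  expect_gte(min(vapply(fit$clusters, `[[`, 0, "p_uncorrected")), 1 / 101)
})

test_that("identical subjects give degenerate p-values of 1", {
  z <- matrix(0.3, 5, 5)
  zs <- lapply(1:8, function(i) make_conn(z, sprintf("s%d", i)))
  grp <- setNames(rep(c("A", "B"), each = 4), names(zs) <- sprintf("s%d", 1:8))
  des <- study_design(names(zs), grp, seed = 1)
  fit <- suppressWarnings(tfce_test(zs, des, c("A", "B"),
                                    n_permutations = 100, seed = 2))
  expect_equal(fit$global_peak, 0)
  expect_equal(fit$global_peak_p_fwe, 1)
  expect_true(all(fit$null_peaks == 0))
  expect_length(fit$clusters, 0)
})

test_that("tfce_test is reproducible given a seed and respects determinism", {
  ch <- sim_cohort(n_hc = 8, n_ad = 8, n_t = 80, seed = 14)
  f1 <- tfce_test(ch$z_matrices, ch$design, c("HC", "AD"),
                  n_permutations = 120, seed = 7)
  f2 <- tfce_test(ch$z_matrices, ch$design, c("HC", "AD"),
                  n_permutations = 120, seed = 7)
  expect_identical(f1$null_peaks, f2$null_peaks)
  expect_identical(f1$tfce_map, f2$tfce_map)
  expect_identical(summary(f1), summary(f2))
  f3 <- tfce_test(ch$z_matrices, ch$design, c("HC", "AD"),
                  n_permutations = 120, seed = 8)
  expect_false(identical(f1$null_peaks, f3$null_peaks))
})

test_that("planted cluster is detected and localized", {
  ch <- sim_cohort(n_hc = 25, n_ad = 25, n_t = 200, seed = 15, delta_z = 0.4)
  fit <- tfce_test(ch$z_matrices, ch$design, c("HC", "AD"),
                   n_permutations = 200, atlas = default_atlas())
  expect_gt(length(fit$clusters), 0)
  sig <- Filter(function(cl) cl$peak_p_fwe < 0.05, fit$clusters)
  expect_gt(length(sig), 0)
  top <- sig[[which.max(vapply(sig, `[[`, 0, "mass"))]]
  expect_equal(top$sign, "positive")  # HC > AD on planted edges
  expect_gte(jaccard(cluster_edge_keys(top), planted_edge_keys()), 0.3)
  expect_true(all(c("DefaultMode") %in% top$networks_involved))
})

test_that("nbs components match the union-find toy example", {
  # 5-ROI map with suprathreshold edges {(1,2),(2,3),(4,5)}
  tm <- matrix(0, 5, 5)
  tm[1, 2] <- tm[2, 1] <- 4
  tm[2, 3] <- tm[3, 2] <- 3.5
  tm[4, 5] <- tm[5, 4] <- -3.2
  comps <- conntfce:::nbs_components(tm, 3)
  sizes <- sort(vapply(comps, `[[`, 0L, "size"))
  expect_equal(sizes, c(1L, 2L))
  # cross-check against the oracle component labelling, per tail
  lab_pos <- oracle_label_edge_graph(tm > 3)
  expect_equal(max(lab_pos), 1)
  expect_equal(sum(lab_pos > 0) / 2, 2)

  expect_length(conntfce:::nbs_components(tm, 10), 0)
  # one component containing all suprathreshold edges conserves the count
  tm2 <- matrix(0, 5, 5)
  tm2[1, 2] <- tm2[2, 1] <- 4; tm2[2, 3] <- tm2[3, 2] <- 4
  tm2[3, 4] <- tm2[4, 3] <- 4
  c2 <- conntfce:::nbs_components(tm2, 3)
  expect_length(c2, 1)
  expect_equal(c2[[1]]$size, 3L)
})

test_that("nbs on simulated data finds the planted component", {
  ch <- sim_cohort(n_hc = 25, n_ad = 25, n_t = 200, seed = 16, delta_z = 0.4)
  res <- nbs(ch$z_matrices, ch$design, c("HC", "AD"), edge_threshold = 3,
             n_permutations = 200)
  expect_gt(length(res$components), 0)
  top <- res$components[[1]]
  expect_lt(top$p_fwe, 0.05)
  expect_equal(top$sign, "positive")
  expect_gt(jaccard(cluster_edge_keys(top), planted_edge_keys()), 0.2)
})

test_that("TFCE and NBS agree on the top edges of a strong compact cluster", {
  ch <- sim_cohort(n_hc = 20, n_ad = 20, n_t = 250, seed = 17, delta_z = 0.4)
  fit <- tfce_test(ch$z_matrices, ch$design, c("HC", "AD"),
                   n_permutations = 100)
  res <- nbs(ch$z_matrices, ch$design, c("HC", "AD"), edge_threshold = 3,
             n_permutations = 100)
  top_t <- fit$clusters[[1]]$edges
  top_n <- res$components[[1]]$edges
  top5 <- function(e) {
    e <- e[order(-abs(e$stat)), ]
    paste(pmin(e$roi_a, e$roi_b), pmax(e$roi_a, e$roi_b))[seq_len(min(5, nrow(e)))]
  }
  expect_gte(length(intersect(top5(top_t), top5(top_n))), 3)
})

test_that("report extraction and round-trip serialization", {
  ch <- sim_cohort(n_hc = 10, n_ad = 10, n_t = 100, seed = 18, delta_z = 0.4)
  fit <- tfce_test(ch$z_matrices, ch$design, c("HC", "AD"),
                   n_permutations = 100, atlas = default_atlas())
  rep_df <- extract_report(fit, default_atlas())
  expect_true(all(c(rep_df$roi_a, rep_df$roi_b) %in% default_atlas()$roi_labels))
  # within each cluster edges are ordered by |stat| descending
  for (cl in unique(rep_df$cluster)) {
    s <- abs(rep_df$stat[rep_df$cluster == cl])
    expect_true(all(diff(s) <= 1e-12))
  }
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep_df, f)
  expect_identical(read_report(f), rep_df)
  # idempotent: write o read o write
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(read_report(f), f2)
  expect_identical(readLines(f), readLines(f2))

  empty <- extract_report(structure(list(clusters = list()),
                                    class = "tfce_test"))
  expect_equal(nrow(empty), 0)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write_report(empty, f3)
  expect_identical(nrow(read_report(f3)), 0L)
})

test_that("permutation scheme rejects impossible designs", {
  co <- constant_z_cohort(list(A = c(0.1, 0.2), B = c(0.3, 0.4)))
  expect_error(tfce_test(co$z_matrices, co$design, c("A", "B"),
                         n_permutations = 50), ">= 100")
  expect_error(tfce_test(co$z_matrices, co$design, c("A", "C"),
                         n_permutations = 100), ">= 2 subjects")
})
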