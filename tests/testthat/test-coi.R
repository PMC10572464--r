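test_that("cluster mean z is the arithmetic mean over the cluster's edges", {
  labs <- paste0("N.R", 1:4)
  z <- matrix(0, 4, 4)
  z[1, 2] <- z[2, 1] <- 0.2
  z[1, 3] <- z[3, 1] <- 0.4
  zs <- list(s1 = make_conn(z, "s1", labs))
  one <- data.frame(roi_a = "N.R1", roi_b = "N.R2")
  two <- data.frame(roi_a = c("N.R1", "N.R1"), roi_b = c("N.R2", "N.R3"))
  expect_equal(unname(coi_mean_z(one, zs)), 0.2)
  expect_equal(unname(coi_mean_z(two, zs)), 0.3)

  # mean over all edges of a constant matrix is that constant
  zc <- matrix(0.7, 4, 4)
  zsc <- list(s1 = make_conn(zc, "s1", labs))
  all_edges <- as.data.frame(t(combn(labs, 2)))
  names(all_edges) <- c("roi_a", "roi_b")
  expect_equal(unname(coi_mean_z(all_edges, zsc)), 0.7)

  expect_error(coi_mean_z(data.frame(roi_a = character(),
                                     roi_b = character()), zs), "no edges")
  expect_error(coi_mean_z(data.frame(roi_a = "N.R9", roi_b = "N.R1"), zs),
               "not present")
})

test_that("coi ANOVA reproduces the worked example and degenerate cases", {
  ids <- sprintf("s%02d", 1:9)
  grp <- setNames(rep(c("HC", "MCI", "AD"), each = 3), ids)
  des <- study_design(ids, grp, seed = 1)
  mz <- setNames(c(1, 2, 3, 2, 3, 4, 3, 4, 5), ids)
  s <- coi_anova(mz, des)
  expect_equal(s$anova_f, 3, tolerance = 1e-12)
  expect_equal(s$df, c(2, 6))
  expect_equal(s$anova_p, pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  # pairwise t for equal-mean groups is 0
  mz2 <- setNames(rep(c(1, 2, 3), 3), ids)
  s2 <- coi_anova(mz2, des)
  expect_true(all(s2$pairwise$t == 0))
  expect_equal(s2$anova_f, 0)
  expect_equal(s2$anova_p, 1)

  # identical constant groups: F = 0, p = 1 by convention
  mzc <- setNames(rep(1, 9), ids)
  sc <- coi_anova(mzc, des)
  expect_equal(sc$anova_f, 0)
  expect_equal(sc$anova_p, 1)
})

test_that("two-group ANOVA F equals the squared pairwise t", {
  ids <- sprintf("s%02d", 1:10)
  grp <- setNames(rep(c("HC", "AD"), each = 5), ids)
  des <- study_design(ids, grp, seed = 1)
  set.seed(9)
  mz <- setNames(rnorm(10), ids)
  s <- coi_anova(mz, des)
  expect_equal(s$anova_f, s$pairwise$t[1]^2, tolerance = 1e-10)
})

test_that("the reporting rule is a pure function of R and p", {
  expect_true(reporting_rule(0.4, 0.01))
  expect_true(reporting_rule(-0.4, 0.01))
  expect_false(reporting_rule(0.3, 0.01))   # |R| too small
  expect_false(reporting_rule(0.4, 0.06))   # p too large
  expect_false(reporting_rule(-0.08, 0.01)) # sub-threshold |R| never passes
})

test_that("cdr correlation recovers exact and error cases", {
  ids <- sprintf("s%02d", 1:12)
  grp <- setNames(rep("AD", 12), ids)
  set.seed(10)
  mz <- setNames(rnorm(12), ids)
  cdr <- setNames(2 * mz[ids] + 1, ids)  # exactly linear, positive slope
  des <- study_design(ids, grp, cdr = cdr, seed = 1)
  res <- cdr_correlation(mz, design = des, group = "AD")
  expect_equal(res$R, 1, tolerance = 1e-12)
  expect_equal(res$R2, res$R^2)
  expect_true(res$passes_reporting_rule)
  expect_equal(res$n, 12)

  des0 <- study_design(ids, grp, cdr = setNames(rep(1, 12), ids), seed = 1)
  expect_error(cdr_correlation(mz, design = des0, group = "AD"),
               "zero variance")
  expect_error(cdr_correlation(mz, design = des, group = "HC"), ">= 4")
})

test_that("full coi path runs on a fitted comparison", {
  ch <- sim_cohort(n_hc = 12, n_ad = 12, n_t = 150, seed = 19, delta_z = 0.4)
  fit <- tfce_test(ch$z_matrices, ch$design, c("HC", "AD"),
                   n_permutations = 100, atlas = default_atlas())
  cl <- fit$clusters[[1]]
  mz <- coi_mean_z(cl, ch$z_matrices)
  expect_length(mz, 24)
  s <- coi_anova(mz, ch$design, cluster_id = "COI1")
  expect_s3_class(s, "coi_summary")
  expect_lt(s$anova_p, 0.05)  # strong planted effect
  r <- cdr_correlation(cl, ch$z_matrices, ch$design, "AD")
  expect_true(is.finite(r$R))
  expect_equal(r$n, 12)
})
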