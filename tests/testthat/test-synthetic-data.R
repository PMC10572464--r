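test_that("zero loading and no planted edges give null connectivity", {
  sc <- simulation_scenario(n_per_group = c(HC = 50), n_timepoints = 200,
                            within_network_loading = 0, planted_edges = NULL,
                            seed = 11)
  ch <- generate_cohort(sc)
  zs <- lapply(ch$timeseries, function(ts) connectivity(ts)$z)
  n <- nrow(zs[[1]])
  ut <- upper.tri(zs[[1]])
  edge_means <- Reduce(`+`, zs)[ut] / length(zs)
  # per-edge standard error of the mean z: ~ 1/sqrt(T-3) / sqrt(n_subj)
  se <- 1 / sqrt(200 - 3) / sqrt(50)
  expect_lt(mean(abs(edge_means) > 3 * se), 0.02)  # expected ~0.3%
  expect_lt(abs(mean(edge_means)), 3 * se)
})

test_that("shared-signal loading yields the derived within-network correlation", {
  # closed form: corr = lambda^2 for unit-variance shared signal plus
  # independent noise of variance 1 - lambda^2; verified independently by
  # direct large-T simulation of that two-ROI model
  lam <- 0.6
  set.seed(1)
  Tbig <- 2e5
  L <- rnorm(Tbig)
  x <- lam * L + sqrt(1 - lam^2) * rnorm(Tbig)
  y <- lam * L + sqrt(1 - lam^2) * rnorm(Tbig)
  expect_lt(abs(cor(x, y) - lam^2), 0.01)

  sc <- simulation_scenario(n_per_group = c(HC = 100), n_timepoints = 200,
                            within_network_loading = lam, planted_edges = NULL,
                            seed = 12)
  ch <- generate_cohort(sc)
  atl <- default_atlas()
  net <- atl$network_of[atl$roi_labels]
  same_net <- outer(net, net, "==") & upper.tri(diag(32))
  rs <- vapply(ch$timeseries, function(ts) mean(cor(ts$data)[same_net]),
               numeric(1))
  expect_lt(abs(mean(rs) - lam^2), 0.01)
})

test_that("cohort generation is a pure function of the seed", {
  sc <- simulation_scenario(n_per_group = c(HC = 3, AD = 3),
                            n_timepoints = 50, seed = 5)
  a <- generate_cohort(sc)
  b <- generate_cohort(sc)
  expect_identical(lapply(a$timeseries, `[[`, "data"),
                   lapply(b$timeseries, `[[`, "data"))
  expect_identical(a$design$cdr, b$design$cdr)
  # and does not disturb the caller's RNG
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(generate_cohort(sc)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("planted edges reduce group z by delta_z; null edges unaffected", {
  delta <- 0.4
  sc <- simulation_scenario(n_per_group = c(HC = 50, AD = 50),
                            n_timepoints = 500,
                            planted_edges = default_planted_edges(delta),
                            affected_group = "AD", seed = 13)
  ch <- generate_cohort(sc)
  zs <- lapply(ch$timeseries, connectivity)
  st <- stack_z(zs)
  grp <- ch$design$group_of[rownames(st$Z)]
  diff <- colMeans(st$Z[grp == "HC", ]) - colMeans(st$Z[grp == "AD", ])
  la <- st$roi_labels[st$pairs[, 1]]
  lb <- st$roi_labels[st$pairs[, 2]]
  keys <- paste(pmin(la, lb), pmax(la, lb), sep = " ~ ")
  planted <- keys %in% planted_edge_keys(default_planted_edges(delta))
  expect_equal(sum(planted), 10)
  # 3 Monte-Carlo standard errors: per-edge se of the mean-z difference
  se <- sqrt(2 / (50 * (500 - 3)))
  expect_lt(abs(mean(diff[planted]) - delta), 3 * se)
  expect_lt(abs(mean(diff[!planted])), 3 * se)
})

test_that("planted-edge configuration errors are caught", {
  expect_error(generate_cohort(simulation_scenario(
    n_per_group = c(HC = 2, AD = 2), n_timepoints = 50,
    planted_edges = data.frame(roi_a = "DefaultMode.MPFC", roi_b = "NoSuch.ROI",
                               delta_z = 0.4), seed = 1)),
    "unknown ROI")
  expect_error(simulation_scenario(
    n_per_group = c(HC = 2, AD = 2),
    planted_edges = data.frame(roi_a = "a", roi_b = "b", delta_z = Inf)),
    "finite")
  # a massive reduction on many edges breaks positive definiteness
  expect_error(generate_cohort(simulation_scenario(
    n_per_group = c(HC = 2, AD = 2), n_timepoints = 50,
    planted_edges = default_planted_edges(5), seed = 1)),
    "positive-definite")
})

test_that("cdr couples negatively to planted-cluster connectivity", {
  sc <- simulation_scenario(n_per_group = c(HC = 40, AD = 40),
                            n_timepoints = 200, seed = 21)
  ch <- generate_cohort(sc)
  cdr <- ch$design$cdr
  grp <- ch$design$group_of
  expect_true(all(cdr >= 0 & cdr <= 3))
  # affected group loses connectivity, hence higher CDR
  expect_gt(mean(cdr[grp == "AD"]), mean(cdr[grp == "HC"]) + 0.3)
  expect_true(all(ch$design$mmse >= 0 & ch$design$mmse <= 30))
  expect_lt(mean(ch$design$mmse[grp == "AD"]),
            mean(ch$design$mmse[grp == "HC"]))
})

test_that("nuisance traces spike the configured number of timepoints", {
  sc0 <- simulation_scenario(n_per_group = c(HC = 2), n_timepoints = 200,
                             planted_edges = NULL, spike_fraction = 0, seed = 3)
  nu0 <- generate_nuisance(sc0)
  expect_true(all(vapply(nu0, function(d) all(d$fd <= 0.9), TRUE)))
  expect_true(all(vapply(nu0, function(d) nrow(d) == 200L, TRUE)))

  sc5 <- simulation_scenario(n_per_group = c(HC = 3), n_timepoints = 200,
                             planted_edges = NULL, spike_fraction = 0.05,
                             seed = 3)
  nu5 <- generate_nuisance(sc5)
  expect_true(all(vapply(nu5, function(d) sum(d$fd > 0.9) == 10L, TRUE)))

  expect_identical(generate_nuisance(sc5), generate_nuisance(sc5))
})
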