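test_that("hierarchical sorting makes block structure contiguous", {
  # two 3-ROI blocks with strong within-block z, near-zero between
  labs <- paste0("N.R", 1:6)
  block <- matrix(0.05, 6, 6)
  block[1:3, 1:3] <- 0.8
  block[4:6, 4:6] <- 0.8
  diag(block) <- 0
  set.seed(7)
  zs <- lapply(1:4, function(i)
    make_conn(block + matrix(rnorm(36, sd = 0.01), 6, 6), paste0("s", i), labs))
  zs <- lapply(zs, function(m) { m$z <- (m$z + t(m$z)) / 2; diag(m$z) <- 0; m })
  ord <- sort_rois(zs)
  memb <- rep(1:2, each = 3)[ord]
  expect_true(all(diff(which(memb == 1)) == 1))  # block 1 contiguous
  expect_true(all(diff(which(memb == 2)) == 1))  # block 2 contiguous

  # two ROIs: tie-broken to input order
  zs2 <- list(make_conn(matrix(c(0, .3, .3, 0), 2), "s1", c("N.a", "N.b")))
  expect_equal(sort_rois(zs2), 1:2)
})

test_that("enhancement matches the brute-force oracle on random maps", {
  set.seed(31)
  for (i in 1:15) {
    m <- random_stat_map(6)
    for (nb in c("matrix_image_4", "edge_graph")) {
      got <- tfce_enhance(m, params = tfce_params(neighborhood = nb,
                                                  n_steps = 40))
      want <- oracle_tfce(m, n_steps = 40, neighborhood = nb)
      expect_lt(max(abs(got - want)) / max(abs(want)), 1e-10)
    }
  }
})

test_that("single-edge map approaches the closed-form v^(H+1)/(H+1)", {
  v <- 3
  m <- matrix(0, 8, 8)
  m[2, 5] <- m[5, 2] <- v
  for (nb in c("matrix_image_4", "edge_graph")) {
    enh <- tfce_enhance(m, params = tfce_params(neighborhood = nb))
    expect_equal(enh[2, 5], v^3 / 3, tolerance = 0.02)
    expect_equal(enh[5, 2], enh[2, 5])
    expect_equal(sum(enh != 0), 2)
  }
  # convergence: more steps gets closer to the limit
  e1 <- tfce_enhance(m, params = tfce_params(n_steps = 20))[2, 5]
  e2 <- tfce_enhance(m, params = tfce_params(n_steps = 2000))[2, 5]
  expect_lt(abs(e2 - 9), abs(e1 - 9))
})

test_that("uniform map gives the closed-form m^E * v^(H+1)/(H+1)", {
  K <- 6; v <- 2
  m_edges <- K * (K - 1) / 2
  u <- matrix(v, K, K); diag(u) <- 0
  for (nb in c("matrix_image_4", "edge_graph")) {
    enh <- tfce_enhance(u, params = tfce_params(neighborhood = nb,
                                                n_steps = 400))
    off <- upper.tri(u)
    expect_equal(unname(enh[off]),
                 rep(sqrt(m_edges) * v^3 / 3, sum(off)), tolerance = 0.01)
  }
  # cross-checked against the brute-force oracle
  expect_equal(tfce_enhance(u, params = tfce_params(neighborhood = "edge_graph",
                                                    n_steps = 50)),
               oracle_tfce(u, n_steps = 50, neighborhood = "edge_graph"),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("all-zero map enhances to all zeros", {
  z <- matrix(0, 5, 5)
  expect_true(all(tfce_enhance(z) == 0))
})

test_that("scaling the map by c > 1 strictly increases nonzero scores", {
  set.seed(41)
  m <- random_stat_map(8)
  p <- tfce_params()
  a <- tfce_enhance(m, params = p)
  b <- tfce_enhance(2 * m, params = p)
  nz <- a != 0
  expect_true(all(abs(b[nz]) > abs(a[nz])))
  expect_true(all(sign(b[nz]) == sign(a[nz])))
})

test_that("doubling the step count changes scores by less than 1%", {
  # smooth map: a planted-effect contrast
  ch <- sim_cohort(n_hc = 12, n_ad = 12, n_t = 120, seed = 8)
  tm <- two_sample_t_map(ch$z_matrices, ch$design, "HC", "AD")
  ord <- sort_rois(ch$z_matrices)
  for (nb in c("matrix_image_4", "edge_graph")) {
    a <- tfce_enhance(tm, ord, tfce_params(n_steps = 100, neighborhood = nb))
    b <- tfce_enhance(tm, ord, tfce_params(n_steps = 200, neighborhood = nb))
    # map-level relative change; individual near-zero edges may jump
    # between discrete component memberships
    expect_lt(sqrt(sum((b - a)^2) / sum(a^2)), 0.01)
  }
})

test_that("two-sided enhancement treats the tails antisymmetrically", {
  set.seed(51)
  m <- random_stat_map(7)
  p <- tfce_params()
  expect_equal(tfce_enhance(-m, params = p), -tfce_enhance(m, params = p))
  # one-sided ignores the negative tail
  p1 <- tfce_params(two_sided = FALSE)
  pos_only <- tfce_enhance(m, params = p1)
  expect_true(all(pos_only >= 0))
})

test_that("roi_order only permutes image-space components, not edge-graph scores", {
  set.seed(61)
  m <- random_stat_map(8)
  ord <- sample(8)
  pg <- tfce_params(neighborhood = "edge_graph")
  expect_equal(tfce_enhance(m, ord, pg), tfce_enhance(m, NULL, pg))
})
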