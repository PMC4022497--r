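# Centre of interface, energy-centrality regression, the eight features,
# and the plotting projection.

test_that("centre of interface is the C-alpha mean and dr the Euclidean distance", {
  sq <- make_interface(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)))
  g <- center_of_interface(sq)
  expect_equal(unname(g$coi), c(0, 0, 0))
  expect_equal(g$dr, rep(1, 4))

  single <- make_interface(matrix(c(3, -2, 5), 1, 3), chain = "A")
  g1 <- center_of_interface(single)
  expect_equal(unname(g1$coi), c(3, -2, 5))
  expect_equal(g1$dr, 0)

  set.seed(11)
  xyz <- matrix(rnorm(21, sd = 5), 7, 3)
  g7 <- center_of_interface(make_interface(xyz))
  expect_equal(unname(g7$coi), colMeans(xyz))
  expect_equal(g7$dr, sqrt(colSums((t(xyz) - colMeans(xyz))^2)))

  empty <- make_interface(matrix(numeric(0), 0, 3), chain = character(0))
  expect_error(center_of_interface(empty), class = "ecr_degenerate_error")
})

test_that("energy-centrality regression matches exact and degenerate cases", {
  # collinear relationship: ddG = 2 - dr
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  g <- center_of_interface(make_interface(xyz))
  iface <- make_interface(xyz, ddg = 2 - g$dr)
  fit <- fit_energy_centrality(iface)
  expect_equal(fit$slope, -1, tolerance = 1e-12)
  expect_equal(fit$intercept, 2, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # constant response: slope 0, r2 defined as 0
  flat <- make_interface(xyz, ddg = rep(1.5, 4))
  ffit <- fit_energy_centrality(flat)
  expect_equal(ffit$slope, 0)
  expect_equal(ffit$intercept, 1.5)
  expect_identical(ffit$r2, 0)

  # fewer than 3 residues with ddG
  few <- make_interface(xyz, ddg = c(1, 2, NA, NA))
  expect_error(fit_energy_centrality(few), class = "ecr_degenerate_error")

  # all residues equidistant from the centre
  ring <- make_interface(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)),
                         ddg = c(1, 2, 3, 4))
  expect_error(fit_energy_centrality(ring), class = "ecr_degenerate_error")
})

test_that("regression agrees with the closed-form OLS oracle on random instances", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    xyz <- matrix(rnorm(3 * n, sd = 6), n, 3)
    ddg <- rnorm(n, 0.5, 1.5)
    iface <- make_interface(xyz, ddg = ddg)
    g <- center_of_interface(iface)
    fit <- fit_energy_centrality(iface, g)
    oracle <- ols_oracle(g$dr, ddg)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
    expect_equal(fit$r2, oracle$r2, tolerance = 1e-10)
  }
})

test_that("the eight features follow their definitions, with a strict hot threshold", {
  set.seed(3)
  xyz <- matrix(rnorm(12, sd = 4), 4, 3)
  iface <- make_interface(xyz, ddg = c(2.0, 1.5, 0.5, -0.5))
  fe <- compute_features(iface)
  expect_equal(fe$n_hot, 2)
  expect_equal(fe$sum_ddg, 3.5)
  expect_equal(fe$avg_ddg, 0.875)
  expect_equal(fe$frac_hot, 0.5)
  expect_equal(fe$n_total, 4)

  # exactly +1 kcal/mol is not hot; all cold gives zero
  border <- compute_features(make_interface(xyz, ddg = c(1.0, 1.0, 0.9, 1.0000001)))
  expect_equal(border$n_hot, 1)
  cold <- compute_features(make_interface(xyz, ddg = c(1.0, 0.2, -0.3, 0.99)))
  expect_equal(cold$n_hot, 0)
  expect_equal(cold$frac_hot, 0)

  # n_total counts unscanned residues by default, scanned-only on request
  gly <- make_interface(rbind(xyz, c(9, 9, 9)),
                        resname = c("ALA", "SER", "LEU", "VAL", "GLY"),
                        ddg = c(2.0, 1.5, 0.5, -0.5, NA))
  fe_all <- compute_features(gly)
  expect_equal(fe_all$n_total, 5)
  expect_equal(fe_all$frac_hot, 2 / 5)
  fe_scan <- compute_features(gly, total_counts_all = FALSE)
  expect_equal(fe_scan$n_total, 4)
  expect_equal(fe_scan$sum_ddg, fe_all$sum_ddg)
})

test_that("all eight features are invariant under rigid-body motion", {
  set.seed(99)
  base <- generate_flip(ecr_sim_params(n_residues = 25), seed = 31)$interface
  f0 <- compute_features(base)
  for (i in 1:20) {
    f1 <- compute_features(transform_interface(base))
    for (col in ECR_FEATURES) {
      expect_equal(f1[[col]], f0[[col]], tolerance = 1e-9)
    }
  }
})

test_that("the plotting projection matches an eigendecomposition oracle and normalizes ddG", {
  set.seed(14)
  n <- 18
  xyz <- matrix(rnorm(3 * n, sd = c(6, 3, 1)), n, 3, byrow = TRUE)
  ddg <- c(4, rnorm(n - 1, 0, 1.5))
  proj <- plot_projection(make_interface(xyz, ddg = ddg))

  # axes are the leading eigenvectors of the coordinate covariance
  ev <- eigen(stats::cov(xyz), symmetric = TRUE)$vectors
  centred <- sweep(xyz, 2L, colMeans(xyz))
  expect_equal(abs(proj$pc1), abs(centred %*% ev[, 1])[, 1], tolerance = 1e-8)
  expect_equal(abs(proj$pc2), abs(centred %*% ev[, 2])[, 1], tolerance = 1e-8)

  # ddG normalized to max |ddG|: within [-1, 1], one of +/-1 attained
  expect_true(all(abs(proj$ddg_norm) <= 1 + 1e-12))
  expect_true(any(abs(abs(proj$ddg_norm) - 1) < 1e-12))
  expect_true(all(proj$dr_norm <= 1 + 1e-12))
  expect_true(isTRUE(attr(proj, "axis2_defined")))

  # a planar ring projects with in-plane pairwise distances preserved
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  ring <- cbind(5 * cos(th), 5 * sin(th), 0)
  pr <- plot_projection(make_interface(ring, ddg = rnorm(8)))
  d_in <- dist(ring[, 1:2])
  d_pc <- dist(cbind(pr$pc1, pr$pc2))
  expect_equal(as.numeric(d_pc), as.numeric(d_in), tolerance = 1e-8)

  # collinear geometry flags the second axis as undefined
  line <- cbind(seq_len(5), 0, 0)
  pl <- plot_projection(make_interface(line, ddg = rnorm(5)))
  expect_false(attr(pl, "axis2_defined"))
})
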