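test_that("direct least-squares fit recovers circles and ellipses", {
  circ <- ellipse_truth_points(100, 0, 0, 1, 1, 0)
  e <- fit_ellipse(circ)
  expect_lt(max(abs(e$center)), 1e-8)
  expect_lt(abs(e$semi_axes[1] - 1), 1e-8)
  expect_lt(abs(e$semi_axes[2] - 1), 1e-8)

  truth <- list(cx = 0.3, cy = -0.2, a = 1.5, b = 0.7, phi = pi / 6)
  pts <- ellipse_truth_points(200, truth$cx, truth$cy, truth$a, truth$b,
                              truth$phi)
  e2 <- fit_ellipse(pts)
  expect_lt(abs(e2$center[1] - truth$cx), 1e-6)
  expect_lt(abs(e2$center[2] - truth$cy), 1e-6)
  expect_lt(abs(e2$semi_axes[1] - truth$a), 1e-6)
  expect_lt(abs(e2$semi_axes[2] - truth$b), 1e-6)
  expect_lt(abs(e2$rotation_phi - truth$phi), 1e-6)

  noisy <- ellipse_truth_points(200, truth$cx, truth$cy, truth$a, truth$b,
                                truth$phi, noise_sd = 0.05, seed = 31)
  e3 <- fit_ellipse(noisy)
  expect_lt(abs(e3$center[1] - truth$cx), 0.05)
  expect_lt(abs(e3$center[2] - truth$cy), 0.05)
  expect_lt(abs(e3$semi_axes[1] - truth$a), 0.05)
  expect_lt(abs(e3$semi_axes[2] - truth$b), 0.05)
  expect_lt(abs(e3$rotation_phi - truth$phi), 0.05)
})

test_that("degenerate point sets are rejected", {
  expect_error(fit_ellipse(cbind(1:5, 1:5)), "6 points")
  line <- cbind(seq(0, 1, length.out = 20), 2 * seq(0, 1, length.out = 20))
  expect_error(fit_ellipse(line), "degenerate")
})

test_that("ellipse fitting is equivariant under translation and rotation", {
  pts <- ellipse_truth_points(150, 0.1, 0.4, 2, 1, 0.3, noise_sd = 0.01,
                              seed = 32)
  e0 <- fit_ellipse(pts)
  shift <- c(3, -2)
  e_t <- fit_ellipse(sweep(pts, 2, -shift))
  expect_equal(e_t$center, e0$center + shift, tolerance = 1e-6)
  expect_equal(e_t$semi_axes, e0$semi_axes, tolerance = 1e-6)
  expect_equal(e_t$rotation_phi, e0$rotation_phi, tolerance = 1e-6)

  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  e_r <- fit_ellipse(pts %*% t(R))
  expect_equal(e_r$center, as.vector(R %*% e0$center), tolerance = 1e-6)
  expect_equal(e_r$semi_axes, e0$semi_axes, tolerance = 1e-6)
  expect_equal((e_r$rotation_phi - e0$rotation_phi) %% pi, th %% pi,
               tolerance = 1e-6)
})

test_that("angular projection matches a dense grid search", {
  e <- fit_ellipse(ellipse_truth_points(50, 0.3, -0.2, 1.5, 0.7, pi / 6))
  # a point on the ellipse projects to its own parametric angle
  for (t0 in c(0.3, 2.0, 5.5)) {
    p <- ellipse_points(e, t0)[1, ]
    expect_lt(abs(project_angle(p, e) - t0), 1e-8)
  }
  expect_error(project_angle(e$center, e), "ambiguity")

  set.seed(33)
  pts <- cbind(runif(100, -2, 3), runif(100, -2, 2))
  grid <- seq(0, 2 * pi, length.out = 1e5 + 1)[-(1e5 + 1)]
  ep <- ellipse_points(e, grid)
  for (i in seq_len(nrow(pts))) {
    d2 <- (ep[, 1] - pts[i, 1])^2 + (ep[, 2] - pts[i, 2])^2
    t_oracle <- grid[which.min(d2)]
    t_fast <- project_angle(pts[i, ], e)
    dd <- abs(t_fast - t_oracle) %% (2 * pi)
    expect_lt(min(dd, 2 * pi - dd), 1e-4)
  }
})

test_that("rolling windows reproduce the brute-force windowed mean", {
  set.seed(34)
  e <- fit_ellipse(ellipse_truth_points(30, 0, 0, 2, 1, 0.4))
  scores <- ellipse_truth_points(50, 0, 0, 2, 1, 0.4, noise_sd = 0.3,
                                 seed = 35)
  expr <- matrix(rnorm(50 * 3), 50, 3,
                 dimnames = list(NULL, c("gA", "gB", "gC")))
  prof <- rolling_profile(scores, expr, e, radius = 0.5, n_anchors = 36,
                          orient = FALSE)
  oracle <- rolling_oracle(scores, expr, e, 0.5, 36)
  expect_identical(prof$n, oracle$n)
  expect_lt(max(abs(prof$mean - oracle$mean), na.rm = TRUE), 1e-12)
  expect_identical(is.na(unname(prof$mean)), is.na(oracle$mean))

  # constant expression gives a constant profile with zero SEM
  const <- matrix(5, 50, 1, dimnames = list(NULL, "k"))
  pc <- rolling_profile(scores, const, e, radius = 0.5, n_anchors = 18,
                        orient = FALSE)
  expect_true(all(pc$mean[pc$n > 0] == 5))
  expect_true(all(pc$sem[pc$n >= 2] == 0))
  expect_true(all(pc$ci_low[pc$n >= 2] == 5))

  expect_error(rolling_profile(scores, expr, e, radius = 1e-6),
               "radius error")
})

test_that("trajectories are oriented by phase order and peak in the right
           sector", {
  sim <- simulate_cells(clean_sim_config(n_cells = 500, n_genes = 300,
                                         seed = 36))
  nz <- normalize_cells(sim$matrix)
  sigs <- truth_signatures(sim)
  sc <- score_phases(nz$norm, sigs)
  s2d <- as.matrix(sc[, c("G1S", "G2M")])
  grp <- sim$matrix$cell_meta$group == "haploid"
  e <- fit_ellipse(s2d[grp, ])
  g2_gene <- sigs$G2[1]
  prof <- rolling_profile(s2d[grp, ], nz$norm[grp, g2_gene, drop = FALSE],
                          e, radius = 0.5, n_anchors = 72,
                          phases = sc$phase[grp])
  expect_true(all(diff(prof$anchor_angles) > 0))
  # cells nearest the profile's peak anchor (located via its parametric
  # angle) are dominated by mid-cycle phases: the G2 program peaks inside
  # the G2-majority sector
  peak_k <- which.max(prof$mean[, 1])
  anchor_xy <- ellipse_points(e, prof$param_angles[peak_k])
  d <- sqrt((s2d[grp, 1] - anchor_xy[1])^2 + (s2d[grp, 2] - anchor_xy[2])^2)
  near <- order(d)[1:30]
  major <- names(which.max(table(sim$truth$cells$true_phase[grp][near])))
  expect_true(major %in% c("S", "G2", "G2M"))
  # with the origin at the G1S peak, the G2 program culminates mid-cycle:
  # within one phase sector of its generating peak two arcs downstream
  circ_d <- abs(prof$anchor_angles[peak_k] - 4 * pi / 5) %% (2 * pi)
  expect_lt(min(circ_d, 2 * pi - circ_d), 2 * pi / 5)
})

test_that("trajectory comparison propagates missingness and finds shifts", {
  set.seed(37)
  e <- fit_ellipse(ellipse_truth_points(30, 0, 0, 2, 1, 0))
  scores <- ellipse_truth_points(80, 0, 0, 2, 1, 0, noise_sd = 0.2,
                                 seed = 38)
  expr <- matrix(rnorm(80), 80, 1, dimnames = list(NULL, "g"))
  p1 <- rolling_profile(scores, expr, e, radius = 0.6, n_anchors = 24,
                        orient = FALSE)
  cmp_same <- compare_trajectories(p1, p1)
  expect_true(all(cmp_same$diff[p1$n > 0] == 0))

  expr2 <- expr + 1
  p2 <- rolling_profile(scores, expr2, e, radius = 0.6, n_anchors = 24,
                        orient = FALSE)
  cmp <- compare_trajectories(p2, p1)
  expect_equal(cmp$diff[p1$n > 0], rep(1, sum(p1$n > 0)))
  # CI width pools both SEMs
  k <- which(p1$n >= 2)[1]
  expect_equal(cmp$ci_high[k] - cmp$diff[k],
               1.96 * sqrt(2) * p1$sem[k], tolerance = 1e-12)
  # missing anchors stay missing
  expect_identical(is.na(cmp$diff), is.na(p1$mean) | is.na(p2$mean))
})
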