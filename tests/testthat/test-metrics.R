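test_that("baseline climb rate reproduces the calibrated straight glide", {
  p <- glider_params()
  expect_equal(baseline_climb_rate(p), -0.75, tolerance = 1e-6)
  # a glider of twice the mass at the same incidence sinks faster
  heavy <- glider_params(m = 2 * 7.75)
  expect_lt(baseline_climb_rate(heavy), baseline_climb_rate(p))
  # the algebraic value matches a long simulated glide within 1%
  tr <- scripted_circler(0, 6, duration = 300, seed = 1,
                         start_on_steady = FALSE)
  expect_equal(tail(tr$vz, 1), baseline_climb_rate(p), tolerance = 0.01)
})

test_that("optimal climb rate solver finds the calibrated steady circle", {
  o <- optimal_climb_rate()
  expect_equal(o$vz_optimal, 0.72, tolerance = 1e-4)
  expect_gt(o$sigma, 0) # circling beats gliding in a thermal
  expect_true(is.finite(o$radius))
  # optional circling: the optimum can never be below the best glide
  expect_gte(o$vz_optimal, baseline_climb_rate())
  # no thermal: circling brings no benefit, optimum is a straight glide
  tiny <- optimal_climb_rate(tp = thermal_params(w_star = 1e-6), z = 500)
  best_glide <- max(steady_turn(0, seq(-5, 15, 0.1))$vz_air)
  expect_equal(tiny$vz_optimal, best_glide, tolerance = 1e-3)
  # monotone in thermal strength
  o2 <- optimal_climb_rate(tp = thermal_params(w_star = 10))
  expect_gte(o2$vz_optimal, o$vz_optimal)
  # grid-refinement stability: halving the grid step moves the optimum < 0.01
  o_half <- optimal_climb_rate(grid_step = 0.25)
  expect_lt(abs(o_half$vz_optimal - o$vz_optimal), 0.01)
})

test_that("efficiency metric reproduces the worked values and affine structure", {
  b <- list(vz_optimal = 0.72, vz_baseline = -0.75)
  expect_equal(efficiency_eta(0.72, b), 1)
  expect_equal(efficiency_eta(-0.75, b), 0)
  expect_equal(round(efficiency_eta(0.42, b), 1), 0.8)
  expect_equal(round(efficiency_eta(0.54, b), 2), 0.88)
  # invariant under a common shift of all three climb rates
  sh <- list(vz_optimal = b$vz_optimal + 2, vz_baseline = b$vz_baseline + 2)
  expect_equal(efficiency_eta(0.42 + 2, sh), efficiency_eta(0.42, b))
  # invariant under common positive scaling
  sc <- list(vz_optimal = 3 * b$vz_optimal, vz_baseline = 3 * b$vz_baseline)
  expect_equal(efficiency_eta(3 * 0.42, sc), efficiency_eta(0.42, b))
  expect_error(efficiency_eta(0.4, list(vz_optimal = -1, vz_baseline = 0)))
})

test_that("efficiency bounds come out ordered from the solvers", {
  b <- efficiency_bounds()
  expect_gt(b$vz_optimal, b$vz_baseline)
  expect_equal(b$vz_optimal, 0.72, tolerance = 1e-4)
  expect_equal(b$vz_baseline, -0.75, tolerance = 1e-6)
})

test_that("fraction_in_thermal counts 1 Hz samples inside the radius", {
  tr <- tibble::tibble(t = 0:9, x = c(rep(0, 5), rep(200, 5)), y = 0,
                       u = 0)
  expect_equal(fraction_in_thermal(tr), 0.5)
  expect_equal(fraction_in_thermal(dplyr::mutate(tr, x = 0)), 1)
  expect_equal(fraction_in_thermal(dplyr::mutate(tr, x = 500)), 0)
  # d_center column takes precedence and tracks the drifted center
  tr2 <- tibble::tibble(t = 0:9, d_center = c(rep(10, 3), rep(90, 7)))
  expect_equal(fraction_in_thermal(tr2), 0.3)
  expect_error(fraction_in_thermal(tr[0, ]))
})

test_that("trajectory summaries concentrate on the circling annulus", {
  tr <- make_circle_track(radius = 35, omega = 0.4, duration = 300)
  tr$u <- 0
  tr$vz <- 1
  # uniform-rate circling: the phase angle sweeps all theta bins evenly
  tr$theta <- ((0.4 * tr$t * 180 / pi + 180) %% 360) - 180
  s <- summarize_trajectories(tr, bounds = list(vz_optimal = 0.72,
                                                vz_baseline = -0.75))
  expect_s3_class(s$stats, "tbl_df")
  # position histogram mass sits on the annulus at the circle radius
  r_bin <- sqrt(s$position_hist$x_bin^2 + s$position_hist$y_bin^2)
  mass_on_annulus <- sum(s$position_hist$count[abs(r_bin - 35) <= 10]) /
    sum(s$position_hist$count)
  expect_gt(mass_on_annulus, 0.95)
  # theta histogram of a uniform-rate circle is uniform within counting error
  th_counts <- tapply(s$theta_vz_hist$count, s$theta_vz_hist$theta_bin, sum)
  expect_lt(max(th_counts) / max(1, min(th_counts)), 2)
  # empty input gives empty histograms, not an error
  s0 <- summarize_trajectories(list())
  expect_equal(nrow(s0$position_hist), 0)
  expect_equal(s0$stats$n_traj, 0L)
})

test_that("thermal-parameter inversion recovers a known forward model", {
  fwd <- optimal_climb_rate(tp = thermal_params(5, 2000))
  fit <- fit_thermal_params(fwd$vz_optimal, fwd$radius,
                            w_grid = seq(4, 6, by = 0.5),
                            z_grid = seq(1500, 2500, by = 250))
  expect_equal(fit$w_star, 5)
  expect_equal(fit$z_star, 2000)
  # infeasible targets are reported with a residual, not silently accepted
  expect_warning(
    bad <- fit_thermal_params(25, 30, w_grid = c(4, 5), z_grid = c(1800, 2000)),
    "residual")
  expect_gt(bad$residual, 0.5)
  expect_error(fit_thermal_params(0.7, 0))
})
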