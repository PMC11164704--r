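test_that("aerodynamic forces scale with dynamic pressure and angles", {
  p <- glider_params()
  ctrl <- control_state(sigma = 20, alpha = 8, beta = 3)
  f1 <- aerodynamic_forces(10, ctrl, p)
  f2 <- aerodynamic_forces(20, ctrl, p)
  expect_equal(unname(f2 / f1), rep(4, 3)) # V^2 scaling
  # beta = 0 gives zero side force; drag is positive regardless
  f0 <- aerodynamic_forces(15, control_state(0, 6, 0), p)
  expect_equal(f0[["C"]], 0)
  expect_gt(f0[["D"]], 0)
  expect_error(aerodynamic_forces(0, ctrl, p))
  expect_error(aerodynamic_forces(-3, ctrl, p))
})

test_that("equations of motion reduce to the printed identities", {
  p <- glider_params()
  st <- glider_state(x = 10, y = -5, z = 600, V = 18, gamma = -4, chi = 33)
  ctrl <- control_state(sigma = 25, alpha = 7)
  d <- derivatives(st, ctrl, c(0, 0, 0), p)
  # dz/dt = V sin(gamma) in still air
  expect_equal(d[["z"]], 18 * sin(-4 * pi / 180))
  expect_equal(d[["x"]], 18 * cos(33 * pi / 180) * cos(-4 * pi / 180))
  expect_equal(d[["y"]], 18 * sin(33 * pi / 180) * cos(-4 * pi / 180))
  # with positive bank and no side force the glider turns (chi-dot > 0)
  expect_gt(d[["chi"]], 0)
  # at the algebraic force balance gamma-dot vanishes
  eq <- steady_turn(25, 7, p)
  st_eq <- glider_state(V = eq$V, gamma = eq$gamma, chi = 0)
  d_eq <- derivatives(st_eq, ctrl, c(0, 0, 0), p)
  expect_equal(d_eq[["gamma"]], 0, tolerance = 1e-10)
  expect_equal(d_eq[["V"]], 0, tolerance = 1e-10)
  # planar glide: sigma = 0 and beta = 0 give chi-dot = 0
  d0 <- derivatives(st, control_state(0, 7, 0), c(0, 0, 0), p)
  expect_equal(d0[["chi"]], 0)
})

test_that("wind enters position rates additively", {
  p <- glider_params()
  st <- glider_state(V = 15, gamma = -5, chi = 0)
  d0 <- derivatives(st, control_state(0, 6), c(0, 0, 0), p)
  dw <- derivatives(st, control_state(0, 6), c(3, -1, 2), p)
  expect_equal(dw[["x"]] - d0[["x"]], 3)
  expect_equal(dw[["y"]] - d0[["y"]], -1)
  expect_equal(dw[["z"]] - d0[["z"]], 2)
  # speed/angle rates depend on the airspeed only
  expect_equal(dw[["V"]], d0[["V"]])
  expect_equal(dw[["gamma"]], d0[["gamma"]])
})

test_that("mechanical energy decays through drag alone in still air", {
  p <- glider_params()
  st <- glider_state(V = 16, gamma = -3, chi = 0)
  ctrl <- control_state(sigma = 30, alpha = 9)
  energy <- function(s) 0.5 * p$m * s[["V"]]^2 + p$m * p$g * s[["z"]]
  E <- numeric(121); E[1] <- energy(st)
  for (i in 1:120) {
    st <- step_glider(st, ctrl, NULL, dt = 0.05, p = p)
    E[i + 1] <- energy(st)
  }
  expect_true(all(diff(E) < 0)) # strictly non-increasing
  # dE/dt = -D V within integration tolerance (fine-step oracle)
  st <- glider_state(V = 16, gamma = -3, chi = 0)
  f <- aerodynamic_forces(st[["V"]], ctrl, p)
  dE_pred <- -f[["D"]] * st[["V"]]
  st2 <- step_glider(st, ctrl, NULL, dt = 0.01, p = p)
  dE_obs <- (energy(st2) - energy(st)) / 0.01
  expect_equal(dE_obs, dE_pred, tolerance = 1e-3)
})

test_that("integrator converges: halving the step barely moves the endpoint", {
  p <- glider_params()
  ctrl <- control_state(sigma = 25, alpha = 8)
  endpoint <- function(dt) {
    s <- glider_state(V = 15, gamma = -5, chi = 0)
    for (i in seq_len(round(200 / dt))) s <- step_glider(s, ctrl, NULL, dt, p = p)
    s[c("x", "y", "z")]
  }
  e1 <- endpoint(0.05)
  e2 <- endpoint(0.025)
  expect_lt(sqrt(sum((e1 - e2)^2)), 0.1) # < 0.1 m over 200 s
})

test_that("steady circling from the integrator matches the algebraic solver", {
  p <- glider_params()
  for (cmd in list(c(30, 6), c(40, 12))) {
    eq <- steady_turn(cmd[1], cmd[2], p)
    tr <- scripted_circler(cmd[1], cmd[2], duration = 100, seed = 1)
    late <- tr[tr$t > 20, ]
    # sink rate within 1%
    expect_equal(mean(late$vz), eq$vz_air, tolerance = 0.01)
    # radius within 1%: half the spread of x over whole loops
    r_obs <- (max(late$x) - min(late$x)) / 2
    expect_equal(r_obs, eq$radius, tolerance = 0.01)
  }
})

test_that("instability detection catches winding, stall and dives", {
  p <- glider_params()
  # steady circling pitch oscillation of < 10 deg: stable
  g_osc <- 0.1 * sin(seq(0, 20, by = 0.05))
  expect_false(detect_instability(g_osc, V = 15, p = p))
  # monotone pitch winding through 360 deg (unwrapped history)
  expect_true(detect_instability(seq(0, 2.1 * 2 * pi, by = 0.1), V = 15, p = p))
  # airspeed through the guard
  expect_true(detect_instability(g_osc, V = 1.9, p = p))
  # a hard pitch-down command (negative lift) destabilizes the simulation
  st <- glider_state(V = 15, gamma = -5)
  res <- thermalsoar:::integrate_interval(st, control_state(0, -30), NULL,
                                          interval = 30, dt = 0.05, p = p)
  expect_identical(res$status, "instability")
})
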