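test_that("bank estimator matches the circular-motion closed form", {
  # uniform circle V = 15, r = 30: continuous closed form
  sigma_cont <- atan(15^2 / (9.81 * 30)) * 180 / pi
  expect_equal(sigma_cont, 37.40, tolerance = 1e-3)
  circ <- make_circle_track(radius = 30, omega = 0.5, duration = 80)
  est <- estimate_bank(circ)
  # 1 Hz second differences carry a sinc^2 bias; stay within 2% of the
  # continuous value
  expect_equal(as.numeric(est), sigma_cont, tolerance = 0.02)
  expect_length(attr(est, "sigma_t"), nrow(circ) - 2)
  # straight track: ~0 with a low-curvature warning
  expect_warning(s0 <- estimate_bank(make_straight_track()), "low-curvature")
  expect_lt(abs(as.numeric(s0)), 0.5)
  expect_error(estimate_bank(circ[1:2, ]))
})

test_that("bank estimator validates within the printed 7% on fixtures", {
  v <- fixture("bank_validation",
               validate_bank_estimator(seeds = 1:20, duration = 200))
  expect_equal(nrow(v), 20)
  expect_true(all(v$sigma_true >= 20 & v$sigma_true <= 45))
  expect_lte(attr(v, "mean_rel_err"), 0.07)
})

test_that("wind estimator cancels closed loops and keeps the drift", {
  # closed circles, no drift -> (0, 0)
  circ <- make_circle_track(radius = 40, omega = 2 * pi / 20, duration = 100)
  w0 <- estimate_wind(circ)
  expect_equal(unname(w0), c(0, 0), tolerance = 1e-9)
  # the same circle on a linear drift -> exactly the drift (linearity)
  wd <- estimate_wind(make_circle_track(radius = 40, omega = 2 * pi / 20,
                                        duration = 100, drift = c(3, 0)))
  expect_equal(unname(wd), c(3, 0), tolerance = 1e-9)
  # translation invariance
  tr <- make_circle_track(radius = 25, omega = 0.4, duration = 90,
                          drift = c(2, -1))
  tr2 <- dplyr::mutate(tr, x = x + 1234, y = y - 987)
  expect_equal(estimate_wind(tr), estimate_wind(tr2))
  # rotation equivariance
  phi <- 0.7; R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  rot <- dplyr::mutate(tr, xr = R[1, 1] * x + R[1, 2] * y,
                       yr = R[2, 1] * x + R[2, 2] * y,
                       x = xr, y = yr)
  expect_equal(unname(estimate_wind(rot)),
               as.numeric(R %*% estimate_wind(tr)), tolerance = 1e-9)
  # short tracks raise the bias warning
  expect_warning(estimate_wind(make_circle_track(duration = 10)),
                 "fewer than two full circles")
})

test_that("wind estimator recovers the wind of a simulated trochoid", {
  tr <- trochoid_fixture()
  w <- estimate_wind(tr)
  expect_equal(w[["wx"]], 3, tolerance = 0.1) # within 10%
  expect_lt(abs(w[["wy"]]), 0.3)
})

test_that("thermalling diameter tends to 2R on analytic circles", {
  # drift -> 0 limit: estimates approach the diameter, and the error stays
  # bounded by the sampling resolution across a grid of drift speeds
  R0 <- 30; om <- 0.5
  errs <- vapply(c(0.02, 0.2, 1, 2, 4), function(drift) {
    tr <- make_circle_track(radius = R0, omega = om, duration = 150,
                            drift = c(drift, 0))
    d <- thermalling_diameter(tr, wind_dir = c(1, 0))
    abs(mean(d$diameter) - 2 * R0)
  }, numeric(1))
  expect_lt(errs[1], 2.5) # near-degenerate triangles still give ~2R
  expect_true(all(errs < 0.05 * 2 * R0)) # within 5% over the drift grid
  # degenerate triangle: coincident base points give the apex distance
  tr <- make_circle_track(radius = R0, omega = om, duration = 150,
                          drift = c(1e-9, 0))
  d <- thermalling_diameter(tr, wind_dir = c(1, 0))
  expect_equal(mean(d$diameter), 2 * R0, tolerance = 0.05)
  # too-short input: empty result with a reason, not an error
  short <- make_circle_track(radius = R0, omega = om, duration = 6)
  out <- thermalling_diameter(short, wind_dir = c(1, 0))
  expect_equal(nrow(out), 0)
  expect_true(!is.null(attr(out, "reason")))
})

test_that("thermalling diameter matches the simulator's steady circle", {
  tr <- trochoid_fixture()
  st <- attr(tr, "steady")
  d <- thermalling_diameter(tr, wind_dir = c(1, 0))
  expect_gte(nrow(d), 4)
  expect_equal(mean(d$diameter), 2 * st$radius, tolerance = 0.15)
  expect_true(all(d$type %in% c("ABA", "BAB")))
  expect_true(all(d$diameter > 0))
})

test_that("segment selection finds consistent circling spans", {
  # pure 200 s circling: one segment covering the track
  circ <- make_circle_track(radius = 40, omega = 15 / 40, duration = 200)
  seg <- select_thermalling_segments(circ)
  expect_equal(nrow(seg), 1)
  expect_gte(seg$duration, 190)
  expect_gte(seg$n_turns, 2)
  # straight glide: nothing
  expect_equal(nrow(select_thermalling_segments(make_straight_track(duration = 150))), 0)
  # 120 s circling then 80 s straight: the circling span, +/-5 s
  R0 <- 40; om <- 15 / R0
  t1 <- 0:120
  x1 <- R0 * cos(om * t1); y1 <- R0 * sin(om * t1)
  vx <- -R0 * om * sin(om * 120); vy <- R0 * om * cos(om * 120)
  t2 <- 1:79
  comp <- tibble::tibble(
    t = 0:199,
    x = c(x1, x1[121] + vx * t2),
    y = c(y1, y1[121] + vy * t2),
    z = 500)
  seg <- select_thermalling_segments(comp)
  expect_equal(nrow(seg), 1)
  expect_lte(seg$start, 5)
  expect_equal(seg$end, 120, tolerance = 5)
  # a 90 s circle is below the duration threshold
  expect_equal(nrow(select_thermalling_segments(
    make_circle_track(radius = 40, omega = 0.4, duration = 90))), 0)
})
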