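# Shared fixtures, built in code and memoised across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, .fixture_cache)) {
    assign(name, force(expr), .fixture_cache)
  }
  get(name, .fixture_cache)
}

# Analytic circle track at 1 Hz: radius R, angular rate omega (rad/s),
# optional linear drift, sense +1 CCW / -1 CW.
make_circle_track <- function(radius = 30, omega = 0.5, duration = 80,
                              drift = c(0, 0), sense = 1, phase = 0,
                              z0 = 500, vz = 0) {
  t <- 0:duration
  ang <- phase + sense * omega * t
  tibble::tibble(
    t = t,
    x = radius * cos(ang) + drift[1] * t,
    y = radius * sin(ang) + drift[2] * t,
    z = z0 + vz * t
  )
}

# Straight constant-velocity track at 1 Hz.
make_straight_track <- function(v = c(15, 0), duration = 60, z0 = 500,
                                vz = -0.75) {
  t <- 0:duration
  tibble::tibble(t = t, x = v[1] * t, y = v[2] * t, z = z0 + vz * t)
}

# A scripted trochoid fixture reused by estimator tests.
trochoid_fixture <- function() {
  fixture("trochoid_u3", scripted_circler(30, wind = wind_config(3),
                                          duration = 200, seed = 2))
}

# A short trained-from-scratch curriculum result reused by the training,
# inspection and acceptance tests (a few minutes of simulated flight).
smoke_training <- function() {
  fixture("smoke_training", suppressWarnings(
    curriculum_train(curriculum_schedule(u_max = c(1, 2), budget = 800),
                     episode_config(), seed = 11, checkpoint_every = 800)
  ))
}

expect_angle_close <- function(a, b, tol = 1e-6) {
  d <- (a - b + 180) %% 360 - 180
  expect_lt(abs(d), tol)
}
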