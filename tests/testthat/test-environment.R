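test_that("theta follows the headwind/tailwind convention", {
  # motion against the wind: theta = 0; with the wind: +/-180
  expect_equal(compute_theta(c(-10, 0), c(1, 0), "CW"), 0)
  expect_equal(compute_theta(c(-10, 0), c(1, 0), "CCW"), 0)
  expect_equal(abs(compute_theta(c(10, 0), c(1, 0), "CW")), 180)
  expect_equal(abs(compute_theta(c(10, 0), c(1, 0), "CCW")), 180)
  expect_error(compute_theta(c(0, 0), c(1, 0), "CW"))
})

test_that("theta increases 0 -> 180 through the headwind-tailwind half-circle", {
  # clockwise circle in a +x wind: heading angle decreases over time
  ang <- seq(180, -179, by = -1) * pi / 180
  th <- vapply(ang, function(a) {
    compute_theta(c(cos(a), sin(a)), c(1, 0), "CW")
  }, numeric(1))
  # starts at headwind (0), rises monotonically to 180, wraps, returns to 0
  expect_equal(th[1], 0)
  expect_equal(th[91], 90)
  expect_true(all(diff(th[1:180]) > 0))
  # counter-clockwise is mirrored but still increases headwind -> tailwind
  ang2 <- seq(180, 539, by = 1) * pi / 180
  th2 <- vapply(ang2, function(a) {
    compute_theta(c(cos(a), sin(a)), c(1, 0), "CCW")
  }, numeric(1))
  expect_equal(th2[1], 0)
  expect_true(all(diff(th2[1:180]) > 0))
})

test_that("theta is invariant under rigid rotation of the scene", {
  set.seed(5)
  for (i in 1:20) {
    v <- stats::rnorm(2)
    phi <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    wd <- c(cos(stats::runif(1, 0, 2 * pi)), sin(stats::runif(1, 0, 2 * pi)))
    for (sense in c("CW", "CCW")) {
      expect_equal(compute_theta(as.numeric(R %*% v), as.numeric(R %*% wd), sense),
                   compute_theta(v, wd, sense), tolerance = 1e-9)
    }
  }
})

test_that("observation normalization maps ranges to [-1, 1] for all buffers", {
  mid <- data.frame(V = 15, vz = 0, sigma = 0, alpha = 0, theta = 0, u = 5)
  hi <- data.frame(V = 30, vz = 5, sigma = 50, alpha = 30, theta = 180, u = 10)
  beyond <- data.frame(V = 99, vz = -99, sigma = 60, alpha = -60,
                       theta = 200, u = 20)
  for (B in 1:9) {
    o_mid <- observe(mid, buffer = B)
    expect_length(o_mid, 6 * (B + 1))
    expect_true(all(o_mid == 0)) # range midpoints map to 0
    o_hi <- observe(hi, buffer = B)
    expect_true(all(o_hi == 1)) # range limits map to +/-1
    o_clip <- observe(beyond, buffer = B)
    expect_true(all(abs(o_clip) == 1)) # clipped outside the range
  }
  # front padding repeats the earliest state
  two <- rbind(mid, hi)
  o <- observe(two, buffer = 3)
  expect_equal(o[1:6], o[7:12]) # padded copies of the first row
  expect_equal(o[19:24], rep(1, 6)) # newest state last
  # zero noise: deterministic
  expect_identical(observe(two, 3), observe(two, 3))
})

test_that("sensor noise perturbs raw values before normalization", {
  h <- data.frame(V = 15, vz = 0, sigma = 0, alpha = 0, theta = 0, u = 5)
  set.seed(9); o1 <- observe(h, buffer = 1, noise_level = c(V = 0.5))
  set.seed(9); o2 <- observe(h, buffer = 1, noise_level = c(V = 0.5))
  set.seed(10); o3 <- observe(h, buffer = 1, noise_level = c(V = 0.5))
  expect_identical(o1, o2)
  expect_false(identical(o1, o3))
  # only the V entries move
  expect_true(all(o1[c(2:6, 8:12)] == 0))
  expect_false(any(o1[c(1, 7)] == 0))
})

test_that("reset draws the documented initial conditions", {
  env <- soaring_env(episode_config(u_range = c(1, 5)))
  o1 <- env_reset(env, seed = 123)
  o2 <- env_reset(env, seed = 123)
  expect_identical(o1, o2) # seeded resets are reproducible
  expect_length(o1, 6 * 9)
  expect_true(all(abs(o1) <= 1))
  st <- env$state
  expect_equal(st[["z"]], 500)
  expect_equal(st[["V"]], 15)
  expect_equal(st[["gamma"]], -5 * pi / 180)
  # the still-air climb component of the initial state: V sin(gamma)
  expect_equal(15 * sin(-5 * pi / 180), -1.3073, tolerance = 1e-4)
  # initial placement on the annulus outside the positive-updraft core
  d0 <- vapply(1:400, function(s) {
    env_reset(env, seed = s)
    sqrt(env$state[["x"]]^2 + env$state[["y"]]^2)
  }, numeric(1))
  expect_true(all(d0 >= 80 - 1e-9))
  expect_true(all(d0 <= 150 + 1e-9))
  u <- vapply(1:50, function(s) {
    env_reset(env, seed = s); env$u_mean
  }, numeric(1))
  expect_true(all(u >= 1 & u <= 5))
})

test_that("actions are clipped at the per-step and absolute limits", {
  env <- soaring_env(episode_config(u_range = c(0, 0)))
  env_reset(env, seed = 1)
  out <- env_step(env, c(20, 0)) # request +20, apply +15
  expect_equal(env$ctrl[["sigma"]], 15)
  # push sigma to its +50 limit and hold it there
  for (i in 1:5) out <- env_step(env, c(15, 0))
  expect_equal(env$ctrl[["sigma"]], 50)
  out <- env_step(env, c(15, 0))
  expect_equal(env$ctrl[["sigma"]], 50)
  # alpha per-step limit
  env_reset(env, seed = 1)
  env_step(env, c(0, 99))
  expect_equal(env$ctrl[["alpha"]], 16) # 6 + 10
})

test_that("reward decomposition follows the shaped design", {
  env <- soaring_env(episode_config(u_range = c(0, 0)))
  env_reset(env, seed = 4)
  out <- env_step(env, c(0, 0))
  r <- out$reward
  expect_named(r, c("vz_term", "p_center", "p_stab", "crash_penalty"))
  # p_center = -d/50
  expect_equal(r[["p_center"]], -out$info$d_center / 50)
  expect_equal(sum(r), r[["vz_term"]] + r[["p_center"]]) # no penalties yet
  # d = 50 m gives exactly -1 (formula check at the boundary)
  expect_equal(-50 / 50, -1)
  # stepping a finished episode is rejected
  env2 <- soaring_env(episode_config(z0 = 100, u_range = c(0, 0)))
  ep <- run_episode(env2, function(o) c(0, 0), seed = 2)
  expect_error(env_step(env2, c(0, 0)), "not active")
})

test_that("stability penalty equals minus the remaining seconds", {
  # drive the glider into a dive partway through the episode
  env <- soaring_env(episode_config(u_range = c(0, 0)))
  obs <- env_reset(env, seed = 6)
  dive_after <- 60
  k <- 0; out <- NULL
  repeat {
    k <- k + 1
    act <- if (k > dive_after) c(0, -10) else c(0, 0)
    out <- env_step(env, act)
    if (out$done) break
  }
  expect_identical(out$info$status, "instability")
  expect_equal(out$reward[["p_stab"]], -(200 - out$info$t))
  expect_lt(out$reward[["p_stab"]], -100) # happened well before timeout
})

test_that("crash ends the episode with the -1000 penalty", {
  env <- soaring_env(episode_config(z0 = 60, u_range = c(0, 0)))
  ep <- run_episode(env, function(o) c(0, 0), seed = 2)
  expect_identical(ep$status, "crash")
  expect_equal(ep$rewards[nrow(ep$rewards), "crash_penalty"][[1]], -1000)
  expect_equal(min(ep$trajectory$z), 0)
})

test_that("episode return satisfies the accounting identity", {
  env <- soaring_env(episode_config(u_range = c(2, 2)))
  ep <- run_episode(env, function(o) c(3, 0), seed = 8)
  tr <- ep$trajectory
  # sum of climb terms telescopes to the net altitude change
  expect_equal(sum(ep$rewards[, "vz_term"]),
               tr$z[nrow(tr)] - tr$z[1], tolerance = 1e-9)
  # return = sum vz - sum d/50 + terminal penalties
  expect_equal(ep$return,
               sum(ep$rewards[, "vz_term"]) + sum(ep$rewards[, "p_center"]) +
                 sum(ep$rewards[, "p_stab"]) + sum(ep$rewards[, "crash_penalty"]),
               tolerance = 1e-9)
  # the logged p_center column reproduces the reward rows
  logged <- tr$reward_pcenter[!is.na(tr$reward_pcenter)]
  expect_equal(sum(logged), sum(ep$rewards[, "p_center"]), tolerance = 1e-9)
})

test_that("episodes are bit-reproducible under a fixed seed", {
  env <- soaring_env(episode_config(u_range = c(0, 4),
                                    noise_level = c(V = 0.1, vz = 0.1)))
  pol <- function(o) c(5 * o[1], -2 * o[2])
  ep1 <- run_episode(env, pol, seed = 21)
  ep2 <- run_episode(env, pol, seed = 21)
  expect_identical(ep1$trajectory, ep2$trajectory)
  expect_identical(ep1$observations, ep2$observations)
  expect_identical(ep1$return, ep2$return)
})

test_that("timeout episodes run the full 200 steps", {
  env <- soaring_env(episode_config(u_range = c(0, 0)))
  ep <- run_episode(env, function(o) c(0, 0), seed = 1)
  expect_identical(ep$status, "timeout")
  expect_equal(nrow(ep$trajectory), 201) # t = 0 .. 200
  expect_equal(nrow(ep$rewards), 200)
  expect_equal(ep$return, sum(ep$rewards), tolerance = 1e-12)
})

test_that("reward ablation variants zero out the right terms", {
  cfgs <- list(vz = "vz", vs = "vz+stab", vc = "vz+center")
  env <- soaring_env(episode_config(z0 = 60, u_range = c(0, 0), reward = "vz"))
  ep <- run_episode(env, function(o) c(0, 0), seed = 2)
  expect_true(all(ep$rewards[, "p_center"] == 0))
  expect_true(all(ep$rewards[, "p_stab"] == 0))
  env <- soaring_env(episode_config(z0 = 60, u_range = c(0, 0),
                                    reward = "vz+center"))
  ep <- run_episode(env, function(o) c(0, 0), seed = 2)
  expect_true(any(ep$rewards[, "p_center"] < 0))
  expect_true(all(ep$rewards[, "p_stab"] == 0))
})
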