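# Episodic soaring environment: observation construction with a memory
# buffer, action limits, shaped reward (climb + centering penalty + stability
# penalty + crash penalty), randomized initialization and optional sensor
# noise. The control loop runs at 1 Hz on top of the 0.05 s physics step.

# Fixed physical ranges used to map each observed variable to [-1, 1].
OBS_RANGES <- list(
  V     = c(0, 30),    # ground speed, m/s
  vz    = c(-5, 5),    # climb rate, m/s
  sigma = c(-50, 50),  # bank angle, deg
  alpha = c(-30, 30),  # angle-of-attack, deg
  theta = c(-180, 180),# angle from wind, deg
  u     = c(0, 10)     # horizontal wind speed, m/s
)

# Trajectory-scale standard deviations of the observed variables, used to
# express relative sensor-noise levels (noise sd = level * scale).
OBS_SCALE_STD <- c(V = 2.3, vz = 2.6, sigma = 11.9, alpha = 5.9,
                   theta = 116.4, u = 1)

#' Episode configuration
#'
#' @param duration Episode length, s. Default 200.
#' @param control_dt Control interval, s. Default 1. Must divide `duration`.
#' @param dt Internal physics step, s. Default 0.05.
#' @param z0,V0,gamma0 Initial altitude (m), airspeed (m/s) and glide angle
#'   (deg). Defaults 500, 15, -5.
#' @param r_init Annulus \[min, max\] of initial horizontal distance from the
#'   thermal center, m. Default c(80, 150): close to, but outside, the
#'   positive-updraft core.
#' @param u_range Wind-speed range \[u_min, u_max\] m/s; each episode draws u
#'   uniformly from it.
#' @param buffer Number of previous 1 s steps kept in the observation memory
#'   (plus the current one). Default 8.
#' @param noise_level Named vector of relative sensor-noise levels (sd as a
#'   multiple of the variable's trajectory-scale sd); names among
#'   `V, vz, sigma, alpha, theta, u`. Default: no noise. The `u` entry is an
#'   absolute sd in m/s.
#' @param gust_std,gust_period Gaussian wind-gust settings passed to
#'   [wind_config()].
#' @param reward One of `"full"` (vz + P_center + P_stab + crash),
#'   `"vz"`, `"vz+stab"`, `"vz+center"` -- the reward-shaping ablations.
#' @return An object of class `episode_config`.
#' @export
episode_config <- function(duration = 200, control_dt = 1, dt = 0.05,
                           z0 = 500, V0 = 15, gamma0 = -5,
                           r_init = c(80, 150), u_range = c(0, 0),
                           buffer = 8, noise_level = NULL,
                           gust_std = 0, gust_period = 20,
                           reward = c("full", "vz", "vz+stab", "vz+center")) {
  reward <- match.arg(reward)
  stopifnot(duration %% control_dt == 0, buffer >= 0,
            length(u_range) == 2, u_range[2] >= u_range[1], u_range[1] >= 0)
  nl <- stats::setNames(rep(0, 6), names(OBS_RANGES))
  if (!is.null(noise_level)) {
    bad <- setdiff(names(noise_level), names(nl))
    if (length(bad)) stop("unknown noise variable(s): ", paste(bad, collapse = ", "))
    nl[names(noise_level)] <- noise_level
  }
  structure(list(duration = duration, control_dt = control_dt, dt = dt,
                 z0 = z0, V0 = V0, gamma0 = gamma0, r_init = r_init,
                 u_range = u_range, buffer = buffer, noise_level = nl,
                 gust_std = gust_std, gust_period = gust_period,
                 reward = reward),
            class = "episode_config")
}

#' Angle from the wind
#'
#' Signed angle theta between the planar (ground) velocity and the upwind
#' direction: theta = 0 is flight against the wind (headwind), theta = +/-180
#' deg is flight with the wind (tailwind). The sign is chosen by the sense of
#' rotation so that theta increases from 0 through 90 to 180 during the
#' headwind-to-tailwind half of a circle for either circling direction
#' (mirrored for counter-clockwise rotation).
#'
#' @param velocity_xy Planar velocity 2-vector, m/s (non-zero).
#' @param wind_direction Unit 2-vector of the wind direction. Default +x.
#' @param rotation_sense `"CW"` or `"CCW"`.
#' @return Angle in degrees in (-180, 180].
#' @export
compute_theta <- function(velocity_xy, wind_direction = c(1, 0),
                          rotation_sense = c("CW", "CCW")) {
  rotation_sense <- match.arg(rotation_sense)
  if (sqrt(sum(velocity_xy^2)) <= 0) stop("zero horizontal velocity: theta undefined")
  wd <- wind_direction / sqrt(sum(wind_direction^2))
  up <- -wd # upwind direction
  a <- unname(atan2(up[1] * velocity_xy[2] - up[2] * velocity_xy[1],
                    up[1] * velocity_xy[1] + up[2] * velocity_xy[2])) / DEG
  th <- if (rotation_sense == "CCW") a else -a
  if (th <= -180) th <- th + 360
  if (th > 180) th <- th - 360
  th
}

# Affine map of a raw variable vector to [-1, 1] with clipping.
normalize_obs <- function(raw) {
  vars <- names(OBS_RANGES)
  out <- vapply(vars, function(v) {
    r <- OBS_RANGES[[v]]
    x <- 2 * (raw[[v]] - r[1]) / (r[2] - r[1]) - 1
    min(1, max(-1, x))
  }, numeric(1))
  stats::setNames(out, vars)
}

#' Build a normalized observation vector from a raw-state history
#'
#' Each of the six observed variables (ground speed V, climb rate vz, bank
#' sigma, angle-of-attack alpha, angle-from-wind theta, wind u) is mapped
#' affinely from its fixed physical range to \[-1, 1\] and clipped; optional
#' Gaussian sensor noise is added to the raw value before normalization. The
#' memory buffer holds the `buffer` previous control steps plus the current
#' one (front-padded with the earliest available state), oldest first.
#'
#' @param history A data frame (or tibble) of raw rows with columns
#'   `V, vz, sigma, alpha, theta, u`, one per control step, oldest first;
#'   the last row is the current state.
#' @param buffer Number of previous steps in the memory.
#' @param noise_level Named relative noise levels (see [episode_config()]).
#' @return Numeric vector of length `6 * (buffer + 1)` in \[-1, 1\],
#'   ordered oldest step first, variables in the order V, vz, sigma, alpha,
#'   theta, u within each step.
#' @export
observe <- function(history, buffer = 8, noise_level = NULL) {
  stopifnot(nrow(history) >= 1)
  n_keep <- buffer + 1
  h <- utils::tail(history, n_keep)
  if (nrow(h) < n_keep) { # front-pad with the earliest state
    pad <- h[rep(1, n_keep - nrow(h)), , drop = FALSE]
    h <- rbind(pad, h)
  }
  nl <- stats::setNames(rep(0, 6), names(OBS_RANGES))
  if (!is.null(noise_level)) nl[names(noise_level)] <- noise_level
  obs <- unlist(lapply(seq_len(n_keep), function(i) {
    raw <- as.list(h[i, ])
    for (v in names(OBS_RANGES)) {
      if (nl[[v]] > 0) {
        sd_abs <- nl[[v]] * OBS_SCALE_STD[[v]]
        raw[[v]] <- raw[[v]] + stats::rnorm(1, 0, sd_abs)
      }
    }
    normalize_obs(raw)
  }))
  unname(obs)
}

#' Create a soaring environment
#'
#' An episodic control environment (reset / step interface) around the
#' point-mass glider in a drifting thermal. State, action and reward follow
#' the nominal study design: 6 observed variables with an 8-step memory,
#' actions (d_sigma, d_alpha) limited to +/-15 and +/-10 deg per 1 s step,
#' bank and angle-of-attack clipped to +/-50 and +/-30 deg, and the shaped
#' reward vz - d/50 with stability (-1 per remaining second) and crash
#' (-1000) penalties.
#'
#' @param cfg An [episode_config()] object.
#' @param gp A [glider_params()] object.
#' @param tp A [thermal_params()] object.
#' @return An environment object of class `soaring_env`. Use [env_reset()]
#'   and [env_step()] to run episodes.
#' @examples
#' env <- soaring_env(episode_config(u_range = c(3, 3)))
#' obs <- env_reset(env, seed = 1)
#' out <- env_step(env, c(5, 0))
#' @export
soaring_env <- function(cfg = episode_config(), gp = glider_params(),
                        tp = thermal_params()) {
  e <- new.env(parent = emptyenv())
  e$cfg <- cfg; e$gp <- gp; e$tp <- tp
  e$active <- FALSE
  class(e) <- c("soaring_env", "environment")
  e
}

#' @export
print.soaring_env <- function(x, ...) {
  cat("<soaring_env>",
      sprintf("duration %gs @ %gs control, u in [%g, %g] m/s, buffer %d, reward '%s'\n",
              x$cfg$duration, x$cfg$control_dt, x$cfg$u_range[1],
              x$cfg$u_range[2], x$cfg$buffer, x$cfg$reward))
  invisible(x)
}

# Run expr under the environment's private RNG stream.
with_env_rng <- function(env, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  if (!is.null(env$rng_state)) assign(".Random.seed", env$rng_state, globalenv())
  on.exit({
    env$rng_state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

# Raw observed variables for the current state of an env.
raw_obs_row <- function(env) {
  gv <- ground_velocity(env$state, env$wind_field, env$t)
  vxy <- gv[c("vx", "vy")]
  speed_xy <- sqrt(sum(vxy^2))
  theta <- if (speed_xy > 1e-9) {
    compute_theta(vxy, c(1, 0), env$rotation_sense)
  } else env$last_theta
  env$last_theta <- theta
  data.frame(V = sqrt(sum(gv^2)), vz = gv[["vz"]],
             sigma = env$ctrl[["sigma"]], alpha = env$ctrl[["alpha"]],
             theta = theta, u = env$u_now)
}

# Update the rotation-sense estimate from the mean heading rate over the
# last 5 s (falls back to the current estimate when flight is straight).
update_rotation_sense <- function(env) {
  h <- env$chi_history
  n <- length(h)
  if (n >= 2) {
    k <- min(n, 6) # 5 s window at 1 Hz
    dchi <- diff(utils::tail(h, k))
    dchi <- (dchi + pi) %% (2 * pi) - pi # unwrap
    m <- mean(dchi)
    if (abs(m) > 1e-6) env$rotation_sense <- if (m > 0) "CCW" else "CW"
  }
  invisible(env)
}

#' Reset the environment to a randomized initial state
#'
#' The glider starts at z = 500 m, airspeed 15 m/s, glide angle -5 deg, with
#' a uniformly random heading, at a uniformly random position on an annulus
#' 80-150 m from the thermal center (which starts at the origin); the wind
#' speed is drawn uniformly from the configured range.
#'
#' @param env A [soaring_env()] object.
#' @param seed Optional integer seed making the episode reproducible.
#' @return The initial observation vector (invisibly also stored in `env`).
#' @export
env_reset <- function(env, seed = NULL) {
  cfg <- env$cfg
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    env$rng_state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  } else if (is.null(env$rng_state)) {
    set.seed(sample.int(.Machine$integer.max, 1))
    env$rng_state <- get(".Random.seed", globalenv())
  }
  with_env_rng(env, {
    heading <- stats::runif(1, 0, 360)
    r0 <- sqrt(stats::runif(1, cfg$r_init[1]^2, cfg$r_init[2]^2))
    phi0 <- stats::runif(1, 0, 2 * pi)
    env$u_mean <- stats::runif(1, cfg$u_range[1], cfg$u_range[2])
  })
  env$wind <- wind_config(env$u_mean, cfg$gust_std, cfg$gust_period)
  env$u_now <- if (cfg$gust_std > 0) with_env_rng(env, sample_gust(env$wind)) else env$u_mean
  env$wind_field <- local({
    e <- env
    function(x, y, z, t) wind_vector(x, y, z, t, e$wind, e$tp,
                                     u_effective = e$u_now)
  })
  env$state <- glider_state(x = r0 * cos(phi0), y = r0 * sin(phi0),
                            z = cfg$z0, V = cfg$V0, gamma = cfg$gamma0,
                            chi = heading)
  env$ctrl <- control_state(sigma = 0, alpha = 6)
  env$t <- 0
  env$active <- TRUE
  env$status <- "running"
  env$last_theta <- 0
  env$rotation_sense <- "CW"
  env$chi_history <- env$state[["chi"]]
  env$history <- raw_obs_row(env)
  env$traj <- list(traj_row(env, NA, NA, NA, NA))
  obs <- with_env_rng(env,
    observe(env$history, cfg$buffer, env$cfg$noise_level))
  env$obs <- obs
  obs
}

# One logged trajectory row (1 Hz schema).
traj_row <- function(env, reward_vz, reward_pcenter, dsigma, dalpha) {
  raw <- utils::tail(env$history, 1)
  ctr <- thermal_center(env$t, env$wind)
  tibble::tibble(
    t = env$t, x = env$state[["x"]], y = env$state[["y"]], z = env$state[["z"]],
    V = raw$V, vz = raw$vz, sigma = env$ctrl[["sigma"]],
    alpha = env$ctrl[["alpha"]], theta = raw$theta, u = env$u_now,
    d_center = sqrt((env$state[["x"]] - ctr[1])^2 + (env$state[["y"]] - ctr[2])^2),
    reward_vz = reward_vz, reward_pcenter = reward_pcenter,
    action_dsigma = dsigma, action_dalpha = dalpha
  )
}

#' Advance the environment by one control interval
#'
#' Clips the requested action to the per-step limits (+/-15 deg bank change,
#' +/-10 deg angle-of-attack change), clips the resulting angles to their
#' ranges, integrates the physics for one control interval, and returns the
#' new observation and the decomposed reward. The episode terminates on
#' crash (z = 0, penalty -1000), instability (penalty -1 per remaining
#' second) or timeout.
#'
#' @param env A [soaring_env()] object with an active episode.
#' @param action Numeric 2-vector `c(d_sigma, d_alpha)` in degrees.
#' @return A list: `observation`, `reward` (named vector with components
#'   `vz_term`, `p_center`, `p_stab`, `crash_penalty` and attribute-free
#'   `total`), `done` flag and `info` list (termination cause, time).
#' @export
env_step <- function(env, action) {
  if (!isTRUE(env$active)) stop("episode is not active; call env_reset()")
  cfg <- env$cfg
  dsig <- min(15, max(-15, action[[1]]))
  dalp <- min(10, max(-10, action[[2]]))
  env$ctrl[["sigma"]] <- min(50, max(-50, env$ctrl[["sigma"]] + dsig))
  env$ctrl[["alpha"]] <- min(30, max(-30, env$ctrl[["alpha"]] + dalp))

  # gusts: resample the effective wind on the gust period
  if (cfg$gust_std > 0 &&
      floor(env$t / cfg$gust_period) !=
      floor((env$t + cfg$control_dt) / cfg$gust_period)) {
    env$u_now <- with_env_rng(env, sample_gust(env$wind))
  }

  z_start <- env$state[["z"]]
  res <- integrate_interval(env$state, env$ctrl, env$wind_field,
                            interval = cfg$control_dt, dt = cfg$dt,
                            t0 = env$t, p = env$gp)
  if (!is.null(res$state)) env$state <- res$state
  env$t <- env$t + res$elapsed
  env$status <- res$status

  crashed <- res$status == "crash"
  unstable <- res$status == "instability"
  timeout <- !crashed && !unstable && env$t >= cfg$duration

  z_end <- if (!is.null(res$state)) env$state[["z"]] else z_start
  ctr <- thermal_center(env$t, env$wind)
  d <- if (!is.null(res$state)) {
    sqrt((env$state[["x"]] - ctr[1])^2 + (env$state[["y"]] - ctr[2])^2)
  } else NA_real_

  vz_term <- (z_end - z_start) / cfg$control_dt
  p_center <- if (is.na(d)) 0 else -d / 50
  p_stab <- if (unstable) -(cfg$duration - env$t) else 0
  crash_pen <- if (crashed) -1000 else 0

  use_center <- cfg$reward %in% c("full", "vz+center")
  use_stab <- cfg$reward %in% c("full", "vz+stab")
  reward <- c(vz_term = vz_term,
              p_center = if (use_center) p_center else 0,
              p_stab = if (use_stab) p_stab else 0,
              crash_penalty = crash_pen)

  done <- crashed || unstable || timeout
  if (!is.null(res$state)) {
    env$chi_history <- c(env$chi_history, env$state[["chi"]])
    update_rotation_sense(env)
    env$history <- rbind(env$history, raw_obs_row(env))
    env$traj[[length(env$traj) + 1L]] <-
      traj_row(env, vz_term, reward[["p_center"]], dsig, dalp)
  }
  obs <- with_env_rng(env,
    observe(env$history, cfg$buffer, cfg$noise_level))
  env$obs <- obs
  if (done) env$active <- FALSE
  list(observation = obs, reward = reward, done = done,
       info = list(status = if (done && timeout) "timeout" else res$status,
                   t = env$t, d_center = d))
}

#' Trajectory log of the current/last episode
#'
#' @param env A [soaring_env()] object.
#' @return A 1 Hz trajectory tibble (TrajectoryCSV schema); row `t = 0` is
#'   the initial state with `NA` reward/action fields.
#' @export
env_trajectory <- function(env) {
  dplyr::bind_rows(env$traj)
}

#' Run a full episode under a policy
#'
#' @param env A [soaring_env()] object.
#' @param policy A function mapping an observation vector to an action
#'   `c(d_sigma, d_alpha)` in degrees.
#' @param seed Optional seed forwarded to [env_reset()].
#' @return A list: `trajectory` (tibble), `observations` (matrix, one row
#'   per control step including the initial one), `rewards` (matrix of
#'   reward terms), `return` (sum of total rewards), `status`.
#' @export
run_episode <- function(env, policy, seed = NULL) {
  obs <- env_reset(env, seed = seed)
  obs_log <- list(obs)
  rew_log <- list()
  repeat {
    out <- env_step(env, policy(obs))
    obs <- out$observation
    obs_log[[length(obs_log) + 1L]] <- obs
    rew_log[[length(rew_log) + 1L]] <- out$reward
    if (out$done) break
  }
  rewards <- do.call(rbind, rew_log)
  list(trajectory = env_trajectory(env),
       observations = do.call(rbind, obs_log),
       rewards = rewards,
       return = sum(rewards),
       status = out$info$status)
}
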