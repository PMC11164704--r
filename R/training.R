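# Curriculum-learning orchestration around the DDPG learner: staged wind
# ranges, carried weights, periodic checkpoints tagged by cumulative
# simulated time, and batch evaluation of checkpoints.

#' Curriculum schedule
#'
#' Ordered training stages, each a wind range \[u_min, u_max\] (m/s) and a
#' simulated-flight budget (s). The nominal protocol widens the wind range
#' over three stages, 0-2, 0-4 and 0-6 m/s; the full-scale budget is
#' 3-5 x 10^6 s per stage, scaled down by default for desk-size runs.
#'
#' @param u_max Vector of stage maximum wind speeds, m/s (non-decreasing).
#' @param u_min Vector (or scalar) of stage minimum wind speeds, m/s.
#' @param budget Vector (or scalar) of per-stage simulated-flight budgets, s.
#' @return A tibble with columns `stage`, `u_min`, `u_max`, `budget`.
#' @examples
#' curriculum_schedule() # nominal stages at reduced budget
#' @export
curriculum_schedule <- function(u_max = c(2, 4, 6), u_min = 0,
                                budget = 2e5) {
  if (is.unsorted(u_max)) stop("stage u_max must be non-decreasing")
  tibble::tibble(stage = seq_along(u_max),
                 u_min = rep_len(u_min, length(u_max)),
                 u_max = u_max,
                 budget = rep_len(budget, length(u_max)))
}

# Fraction of the nominal duration flown before instability/crash.
episode_stable_frac <- function(traj, status, duration) {
  if (status %in% c("timeout", "ok")) 1 else max(traj$t) / duration
}

#' Train an agent through a wind curriculum
#'
#' Runs the DDPG learner stage by stage, carrying weights across stages,
#' with exploration noise during action selection and one gradient update
#' per `train_every` control steps. Emits checkpoints tagged by cumulative
#' simulated time and a per-episode training log. A divergence (10
#' consecutive episodes ending unstable after the return had once exceeded
#' its starting level) is reported via a warning, never silently ignored.
#'
#' @param schedule A [curriculum_schedule()] tibble.
#' @param cfg An [episode_config()]; its `u_range` is overridden per stage.
#' @param agent An existing [ddpg_agent()] to continue training, or `NULL`
#'   to initialize a fresh one (observation dimension from `cfg`).
#' @param gp,tp Glider and thermal parameters.
#' @param seed Integer seed (weights, exploration, episode draws).
#' @param checkpoint_every Simulated seconds between checkpoints (also at
#'   each stage boundary).
#' @param verbose Print per-stage progress.
#' @return A list of class `curriculum_result`: `agent` (final),
#'   `checkpoints` (list of checkpoint lists, tagged with `sim_time`),
#'   `log` (tibble: stage, episode, sim_time, return, status, stable_frac,
#'   frac_in_thermal, mean_vz).
#' @export
curriculum_train <- function(schedule = curriculum_schedule(),
                             cfg = episode_config(), agent = NULL,
                             gp = glider_params(), tp = thermal_params(),
                             seed = 1, checkpoint_every = 1e5,
                             verbose = FALSE) {
  obs_dim <- 6L * (cfg$buffer + 1L)
  set.seed(seed)
  if (is.null(agent)) agent <- ddpg_agent(obs_dim, seed = seed)
  stopifnot(agent$obs_dim == obs_dim)
  log <- list()
  checkpoints <- list()
  next_ckpt <- agent$sim_time + checkpoint_every
  ep <- 0L
  for (si in seq_len(nrow(schedule))) {
    st <- schedule[si, ]
    stage_cfg <- cfg
    stage_cfg$u_range <- c(st$u_min, st$u_max)
    env <- soaring_env(stage_cfg, gp, tp)
    stage_t <- 0
    best_return <- -Inf
    unstable_run <- 0L
    while (stage_t < st$budget) {
      ep <- ep + 1L
      obs <- env_reset(env, seed = seed * 100000L + ep)
      ep_ret <- 0
      repeat {
        a_norm <- actor_forward(agent, matrix(obs, 1))$A
        a_norm <- pmin(1, pmax(-1, as.numeric(a_norm) +
                                 stats::rnorm(agent$act_dim, 0, agent$hp$noise_sd)))
        out <- env_step(env, a_norm * agent$action_scale)
        r <- sum(out$reward)
        ep_ret <- ep_ret + r
        buffer_add(agent, obs, a_norm, r, out$observation, as.numeric(out$done))
        if (agent$buf$writes() %% agent$hp$train_every == 0L) ddpg_update(agent)
        obs <- out$observation
        if (out$done) break
      }
      traj <- env_trajectory(env)
      t_flown <- max(traj$t)
      stage_t <- stage_t + t_flown
      agent$sim_time <- agent$sim_time + t_flown
      status <- out$info$status
      log[[length(log) + 1L]] <- tibble::tibble(
        stage = st$stage, episode = ep, sim_time = agent$sim_time,
        return = ep_ret, status = status,
        stable_frac = episode_stable_frac(traj, status, cfg$duration),
        frac_in_thermal = fraction_in_thermal(traj),
        mean_vz = mean(traj$vz, na.rm = TRUE)
      )
      best_return <- max(best_return, ep_ret)
      unstable_run <- if (status == "instability") unstable_run + 1L else 0L
      if (unstable_run >= 10L && best_return > ep_ret + 100) {
        warning(sprintf(
          "possible divergence: 10 consecutive unstable episodes at stage %d (episode %d)",
          st$stage, ep))
        unstable_run <- 0L
      }
      if (agent$sim_time >= next_ckpt) {
        checkpoints[[length(checkpoints) + 1L]] <- agent_checkpoint(agent)
        next_ckpt <- next_ckpt + checkpoint_every
      }
      if (verbose && ep %% 10L == 0L) {
        message(sprintf("stage %d ep %d sim %.0fs return %.1f (%s)",
                        st$stage, ep, agent$sim_time, ep_ret, status))
      }
    }
    checkpoints[[length(checkpoints) + 1L]] <- agent_checkpoint(agent)
  }
  structure(list(agent = agent, checkpoints = checkpoints,
                 log = dplyr::bind_rows(log)),
            class = "curriculum_result")
}

#' @export
print.curriculum_result <- function(x, ...) {
  cat(sprintf("<curriculum_result> %d episodes, %.3g simulated s, %d checkpoints\n",
              nrow(x$log), x$agent$sim_time, length(x$checkpoints)))
  invisible(x)
}

#' Evaluate an agent at a fixed wind speed
#'
#' Runs `n_runs` seeded episodes with the deterministic policy (no
#' exploration noise) at a fixed horizontal wind `u` and summarizes each
#' run: mean climb rate, soaring efficiency, fraction of time in the
#' thermal, episode return and termination status.
#'
#' @param agent A [ddpg_agent()] object or a checkpoint list.
#' @param u Horizontal wind speed, m/s.
#' @param n_runs Number of evaluation episodes.
#' @param seed Base seed; run i uses `seed + i`.
#' @param cfg An [episode_config()]; `u_range` is overridden to `c(u, u)`.
#' @param gp,tp Glider and thermal parameters.
#' @param bounds Efficiency bounds; computed from `gp`/`tp` when `NULL`.
#' @param keep_trajectories Keep per-run trajectories (in attribute
#'   `trajectories`).
#' @return A tibble of class `soaring_eval`, one row per run: `run`, `u`,
#'   `mean_vz`, `eta`, `frac_in_thermal`, `return`, `status`.
#' @export
evaluate_agent <- function(agent, u, n_runs = 20, seed = 1,
                           cfg = episode_config(), gp = glider_params(),
                           tp = thermal_params(), bounds = NULL,
                           keep_trajectories = FALSE) {
  if (!inherits(agent, "ddpg_agent")) agent <- load_checkpoint(agent)
  out_cols <- tibble::tibble(run = integer(), u = numeric(),
                             mean_vz = numeric(), eta = numeric(),
                             frac_in_thermal = numeric(), return = numeric(),
                             status = character())
  if (n_runs == 0) {
    return(structure(out_cols, class = c("soaring_eval", class(out_cols))))
  }
  if (is.null(bounds)) bounds <- efficiency_bounds(gp, tp)
  cfg$u_range <- c(u, u)
  env <- soaring_env(cfg, gp, tp)
  pol <- agent_policy(agent)
  trajs <- vector("list", n_runs)
  rows <- purrr::map_dfr(seq_len(n_runs), function(i) {
    ep <- run_episode(env, pol, seed = seed + i)
    trajs[[i]] <<- ep$trajectory
    mv <- mean(ep$trajectory$vz, na.rm = TRUE)
    tibble::tibble(run = i, u = u, mean_vz = mv,
                   eta = efficiency_eta(mv, bounds),
                   frac_in_thermal = fraction_in_thermal(ep$trajectory),
                   return = ep$return, status = ep$status)
  })
  res <- structure(rows, class = c("soaring_eval", class(rows)),
                   bounds = bounds)
  if (keep_trajectories) attr(res, "trajectories") <- trajs
  res
}
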