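# Trajectory CSV schema, run-configuration files, and round-trip helpers.
# Angles are degrees, positions meters, one row per second.

TRAJ_COLS <- c("t", "x", "y", "z", "V", "vz", "sigma", "alpha", "theta", "u",
               "d_center", "reward_vz", "reward_pcenter",
               "action_dsigma", "action_dalpha")

TRAJ_UNITS <- paste(
  "# t:s x:m y:m z:m V:m/s vz:m/s sigma:deg alpha:deg theta:deg u:m/s",
  "d_center:m reward_vz:m/s reward_pcenter:- action_dsigma:deg action_dalpha:deg")

#' Write a trajectory to CSV
#'
#' One row per second; a leading comment line documents the units. Columns
#' absent from `traj` are written as `NA` so every file carries the full
#' schema.
#'
#' @param traj Trajectory tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  for (cl in setdiff(TRAJ_COLS, names(traj))) traj[[cl]] <- NA_real_
  traj <- traj[, TRAJ_COLS]
  writeLines(TRAJ_UNITS, path)
  readr::write_csv(traj, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path Path written by [write_trajectory()] (or any CSV with at
#'   least `t`, `x`, `y`, `z` columns; `#` lines are ignored).
#' @return A trajectory tibble.
#' @export
read_trajectory <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_double()))
}

# Recognised configuration sections and keys.
CONFIG_KEYS <- list(
  glider = c("preset", "m", "S", "g", "rho", "C_L0", "C_Lalpha", "C_D0",
             "k_ind", "C_Ybeta", "V_min"),
  thermal = c("w_star", "z_star"),
  wind = c("u", "gust_std", "gust_period"),
  episode = c("duration", "control_dt", "dt", "z0", "V0", "gamma0",
              "r_init", "u_range", "buffer", "reward"),
  training = c("u_max", "u_min", "budget", "checkpoint_every", "lr_actor",
               "lr_critic", "discount", "tau", "batch_size", "buffer_size",
               "noise_sd", "reward_scale", "warmup", "train_every"),
  analysis = c("thermal_radius_m", "k_candidates", "theta_bins"),
  seed = NULL
)

#' Default run configuration
#'
#' Nested configuration (glider / thermal / wind / episode / training /
#' analysis sections plus a seed) matching the nominal study setup.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    glider = list(preset = "vulture"),
    thermal = list(w_star = 5, z_star = 2000),
    wind = list(u = 0, gust_std = 0, gust_period = 20),
    episode = list(duration = 200, control_dt = 1, dt = 0.05, z0 = 500,
                   V0 = 15, gamma0 = -5, r_init = c(80, 150),
                   u_range = c(0, 0), buffer = 8, reward = "full"),
    training = list(u_max = c(2, 4, 6), u_min = 0, budget = 2e5,
                    checkpoint_every = 1e5),
    analysis = list(thermal_radius_m = 80, k_candidates = 1:10,
                    theta_bins = 24),
    seed = 1
  ), class = "run_config")
}

#' Read a run-configuration file
#'
#' YAML with the sections of [default_run_config()]; unknown sections or
#' keys are rejected. Missing keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  bad <- setdiff(names(raw), names(CONFIG_KEYS))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(raw)) {
    if (sec == "seed") { cfg$seed <- raw$seed; next }
    badk <- setdiff(names(raw[[sec]]), CONFIG_KEYS[[sec]])
    if (length(badk)) {
      stop(sprintf("unknown key(s) in [%s]: %s", sec, paste(badk, collapse = ", ")))
    }
    cfg[[sec]][names(raw[[sec]])] <- raw[[sec]]
  }
  cfg
}

#' Write a run configuration to YAML
#'
#' @param cfg A `run_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Build package objects from a run_config.
config_glider <- function(cfg) {
  gl <- cfg$glider
  do.call(glider_params, c(list(preset = gl$preset %||% "vulture"),
                           gl[setdiff(names(gl), "preset")]))
}
config_thermal <- function(cfg) do.call(thermal_params, cfg$thermal)
config_episode <- function(cfg) do.call(episode_config, cfg$episode)
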