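# Scripted (non-learned) fixture generator: constant-control circling or
# gliding runs through the same dynamics as the learning agent. These
# trajectories have known ground truth (bank angle, wind, steady radius) and
# make the estimators and metrics testable without any training.

#' Generate a scripted constant-control trajectory
#'
#' Flies the glider under constant (sigma, alpha) commands for `duration`
#' seconds, sampling the 1 Hz trajectory schema. With a bank the motion
#' settles onto a steady circle in the air frame; under horizontal wind the
#' ground track is a trochoid. By default there is no thermal (uniform wind
#' only), so the track is a pure drifting circle with the algebraic steady
#' state as ground truth.
#'
#' @param sigma_cmd Bank angle command, deg (|sigma| <= 50).
#' @param alpha_cmd Angle-of-attack command, deg (|alpha| <= 30). Default 6.
#' @param wind A [wind_config()] object.
#' @param duration Flight duration, s. Default 200.
#' @param seed Optional seed (randomizes the initial heading; gusts if
#'   configured).
#' @param gp A [glider_params()] object.
#' @param tp Optional [thermal_params()]; `NULL` (default) disables the
#'   thermal so only the uniform wind acts.
#' @param z0,V0 Initial altitude and airspeed. Defaults 500 m, 15 m/s.
#' @param start_on_steady Start from the algebraic steady state of the
#'   commanded turn (default TRUE; otherwise from a -5 deg glide at `V0`).
#' @return A 1 Hz trajectory tibble with attributes `sigma_true`,
#'   `alpha_true`, `u_true`, and (for banked commands) `steady` -- the
#'   [steady_turn()] row. Commands that destabilize the glider stop the
#'   run early with attribute `status = "instability"`.
#' @examples
#' tr <- scripted_circler(30, wind = wind_config(3), duration = 60, seed = 1)
#' attr(tr, "steady")$radius
#' @export
scripted_circler <- function(sigma_cmd, alpha_cmd = 6, wind = wind_config(),
                             duration = 200, seed = NULL,
                             gp = glider_params(), tp = NULL,
                             z0 = 500, V0 = 15, start_on_steady = TRUE) {
  stopifnot(abs(sigma_cmd) <= 50, abs(alpha_cmd) <= 30, duration > 0)
  if (!is.null(seed)) set.seed(seed)
  heading <- stats::runif(1, 0, 360)
  st <- steady_turn(abs(sigma_cmd), alpha_cmd, gp)
  state <- if (start_on_steady) {
    glider_state(x = 0, y = 0, z = z0, V = st$V, gamma = st$gamma,
                 chi = heading)
  } else {
    glider_state(x = 0, y = 0, z = z0, V = V0, gamma = -5, chi = heading)
  }
  ctrl <- control_state(sigma = sigma_cmd, alpha = alpha_cmd)
  u_now <- if (wind$gust_std > 0) sample_gust(wind) else wind$u
  wf_env <- new.env(parent = emptyenv()); wf_env$u_now <- u_now
  wind_field <- function(x, y, z, t) {
    if (is.null(tp)) c(wf_env$u_now, 0, 0)
    else wind_vector(x, y, z, t, wind, tp, u_effective = wf_env$u_now)
  }
  rows <- vector("list", duration + 1)
  mk_row <- function(t, status_ok = TRUE) {
    gv <- ground_velocity(state, wind_field, t)
    vxy <- gv[c("vx", "vy")]
    theta <- if (sqrt(sum(vxy^2)) > 1e-9) {
      compute_theta(vxy, c(1, 0),
                    if (sigma_cmd >= 0) "CCW" else "CW")
    } else NA_real_
    ctr <- thermal_center(t, wind)
    tibble::tibble(
      t = t, x = state[["x"]], y = state[["y"]], z = state[["z"]],
      V = sqrt(sum(gv^2)), vz = gv[["vz"]], sigma = sigma_cmd,
      alpha = alpha_cmd, theta = theta, u = wf_env$u_now,
      d_center = sqrt((state[["x"]] - ctr[1])^2 + (state[["y"]] - ctr[2])^2),
      reward_vz = NA_real_, reward_pcenter = NA_real_,
      action_dsigma = NA_real_, action_dalpha = NA_real_
    )
  }
  rows[[1]] <- mk_row(0)
  status <- "ok"
  n_sec <- as.integer(ceiling(duration))
  for (s in seq_len(n_sec)) {
    if (wind$gust_std > 0 &&
        floor((s - 1) / wind$gust_period) != floor(s / wind$gust_period)) {
      wf_env$u_now <- sample_gust(wind)
    }
    res <- integrate_interval(state, ctrl, wind_field, interval = 1,
                              dt = 0.05, t0 = s - 1, p = gp)
    if (!is.null(res$state)) state <- res$state
    if (res$status != "ok") { status <- res$status; break }
    rows[[s + 1]] <- mk_row(s)
  }
  traj <- dplyr::bind_rows(rows)
  if (status != "ok") {
    warning(sprintf("scripted run stopped early (%s) at t = %g s",
                    status, max(traj$t)))
  }
  attr(traj, "sigma_true") <- sigma_cmd
  attr(traj, "alpha_true") <- alpha_cmd
  attr(traj, "u_true") <- wind$u
  attr(traj, "steady") <- if (abs(sigma_cmd) > 1e-9) st else NULL
  attr(traj, "status") <- status
  traj
}
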