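# Soaring-efficiency metric and the algebraic climb-rate solvers that bound
# it, plus trajectory performance summaries.

#' Steady state of a constant-control turn
#'
#' Algebraic steady state of the glider under constant bank and
#' angle-of-attack in the frame moving with the air mass (beta = 0): the force
#' balance `L cos(sigma) = m g cos(gamma)`, `D = -m g sin(gamma)` gives
#' `tan(gamma) = -C_D / (C_L cos(sigma))`, the equilibrium airspeed
#' `V^2 = 2 m g cos(gamma) / (rho S C_L cos(sigma))`, the turn radius
#' `r = V^2 cos(gamma) / (g tan(sigma))` and the still-air sink rate
#' `V sin(gamma)`.
#'
#' @param sigma Bank angle, deg (>= 0; 0 gives a straight glide, infinite
#'   radius).
#' @param alpha Angle-of-attack, deg.
#' @param p A [glider_params()] object.
#' @return A one-row tibble: `sigma`, `alpha`, `V`, `gamma` (deg), `radius`
#'   (m, `Inf` for straight flight), `vz_air` (m/s, still-air sink).
#' @examples
#' steady_turn(0, 6)   # the baseline straight glide
#' steady_turn(40, 15) # a tight thermalling circle
#' @export
steady_turn <- function(sigma, alpha, p = glider_params()) {
  s <- steady_turn_num(sigma, alpha, p)
  tibble::tibble(
    sigma = sigma, alpha = alpha, V = s$V, gamma = s$gamma / DEG,
    radius = s$radius, vz_air = s$vz_air
  )
}

# Vectorised numeric core of steady_turn (gamma in radians); used inside
# optimisation loops where tibble construction would dominate.
steady_turn_num <- function(sigma, alpha, p) {
  CL <- p$C_L0 + p$C_Lalpha * alpha
  if (any(CL <= 0)) stop("no steady solution: non-positive lift coefficient")
  CD <- p$C_D0 + p$k_ind * CL^2
  sig <- sigma * DEG
  gam <- atan(-CD / (CL * cos(sig)))
  V2 <- 2 * p$m * p$g * cos(gam) / (p$rho * p$S * CL * cos(sig))
  V <- sqrt(V2)
  radius <- ifelse(sigma > 1e-9, V2 * cos(gam) / (p$g * tan(sig)), Inf)
  list(V = V, gamma = gam, radius = radius, vz_air = V * sin(gam))
}

#' Baseline climb rate: best straight glide at alpha = 6 deg
#'
#' Steady-state vertical speed of the straight descending glide at sigma = 0,
#' alpha = 6 deg in still air -- the reference "no thermal" climb rate. With
#' the calibrated vulture-like parameters this is -0.75 m/s.
#'
#' @param p A [glider_params()] object.
#' @param alpha Angle-of-attack of the reference glide, deg. Default 6.
#' @return Climb rate, m/s (negative: sink).
#' @export
baseline_climb_rate <- function(p = glider_params(), alpha = 6) {
  steady_turn(0, alpha, p)$vz_air
}

#' Optimal climb rate: best steady circle inside the thermal
#'
#' Upper bound for the climb rate: over constant-control steady circles
#' (sigma, alpha), the net climb is the still-air sink of the circle plus the
#' updraft at the circle radius, `vz_air(sigma, alpha) + w(r(sigma, alpha),
#' z)`. The solver scans a (sigma, alpha) grid and polishes the best cell
#' with box-constrained local optimisation. The search domain is sigma in
#' \[0, 50\] deg and alpha in \[-5, 15\] deg, the usable pre-stall incidence
#' range of the linear lift closure. With the calibrated parameters and the
#' nominal thermal at z = 500 m the optimum is 0.72 m/s.
#'
#' @param p A [glider_params()] object.
#' @param tp A [thermal_params()] object.
#' @param z Altitude at which the updraft profile is evaluated, m.
#'   Default 500 m (the episode start altitude).
#' @param grid_step Grid spacing in degrees for the initial scan.
#' @return A one-row tibble: `vz_optimal` (m/s) and the argmax `sigma`,
#'   `alpha` (deg), `radius` (m), `V` (m/s).
#' @examples
#' optimal_climb_rate()
#' @export
optimal_climb_rate <- function(p = glider_params(), tp = thermal_params(),
                               z = 500, grid_step = 0.5) {
  lo <- c(0, -5); hi <- c(50, 15)
  net <- function(sa) {
    st <- steady_turn_num(sa[1], sa[2], p)
    w <- if (is.finite(st$radius)) updraft(st$radius, z, tp) else 0
    st$vz_air + w
  }
  grid <- expand.grid(
    sigma = seq(lo[1], hi[1], by = grid_step),
    alpha = seq(lo[2], hi[2], by = grid_step)
  )
  st <- steady_turn_num(grid$sigma, grid$alpha, p)
  w <- ifelse(is.finite(st$radius), updraft(pmin(st$radius, 1e9), z, tp), 0)
  vals <- st$vz_air + w
  if (!any(is.finite(vals))) stop("empty feasible set for the steady-circle solver")
  i <- which.max(vals)
  polish <- stats::optim(
    c(grid$sigma[i], grid$alpha[i]), function(sa) -net(sa),
    method = "L-BFGS-B", lower = lo, upper = hi
  )
  best <- steady_turn_num(polish$par[1], polish$par[2], p)
  tibble::tibble(
    vz_optimal = -polish$value, sigma = polish$par[1], alpha = polish$par[2],
    radius = best$radius, V = best$V
  )
}

#' Climb-rate bounds for the efficiency metric
#'
#' @param p A [glider_params()] object.
#' @param tp A [thermal_params()] object.
#' @param z Altitude for the optimal solver, m.
#' @return A list with `vz_optimal` and `vz_baseline`, m/s.
#' @export
efficiency_bounds <- function(p = glider_params(), tp = thermal_params(),
                              z = 500) {
  b <- list(vz_optimal = optimal_climb_rate(p, tp, z)$vz_optimal,
            vz_baseline = baseline_climb_rate(p))
  if (b$vz_optimal <= b$vz_baseline) stop("degenerate bounds: optimal <= baseline")
  b
}

#' Soaring efficiency
#'
#' Fraction of the available updraft exploited by the agent:
#' \deqn{\eta = \frac{v_z^{agent} - v_z^{baseline}}
#'                   {v_z^{optimal} - v_z^{baseline}}.}
#' `eta = 1` means the full thermal updraft is used, `eta = 0` matches the
#' best straight glide, `eta < 0` is worse than not circling at all. Values
#' outside \[0, 1\] are possible and returned as-is.
#'
#' @param vz_agent Mean climb rate(s) of the agent, m/s. Vectorised.
#' @param bounds A list with `vz_optimal` and `vz_baseline` (see
#'   [efficiency_bounds()]).
#' @return Dimensionless efficiency, same length as `vz_agent`.
#' @examples
#' efficiency_eta(0.42, list(vz_optimal = 0.72, vz_baseline = -0.75)) # ~0.8
#' @export
efficiency_eta <- function(vz_agent, bounds) {
  stopifnot(is.numeric(vz_agent),
            is.numeric(bounds$vz_optimal), is.numeric(bounds$vz_baseline))
  den <- bounds$vz_optimal - bounds$vz_baseline
  if (den <= 0) stop("degenerate bounds: optimal <= baseline")
  (vz_agent - bounds$vz_baseline) / den
}

#' Fraction of flight time spent inside the thermal
#'
#' Fraction of 1 Hz trajectory samples within `radius` metres of the (moving)
#' thermal center -- by default 80 m, the distance out to which the nominal
#' thermal updraft is still positive at soaring altitudes.
#'
#' @param traj A trajectory tibble with a `d_center` column (distance to the
#'   drifted thermal center, m), or with `x`, `y`, `t`, `u` columns from
#'   which it is recomputed.
#' @param radius Thermal membership radius, m. Default 80.
#' @return Fraction in \[0, 1\].
#' @export
fraction_in_thermal <- function(traj, radius = 80) {
  if (nrow(traj) == 0) stop("empty trajectory")
  d <- if ("d_center" %in% names(traj)) traj$d_center
       else sqrt((traj$x - traj$u * traj$t)^2 + traj$y^2)
  mean(d <= radius)
}

#' Performance summary of a set of trajectories
#'
#' Aggregates trajectories into the standard soaring diagnostics: mean climb
#' rate, efficiency, fraction of time in the thermal, distance-to-center
#' statistics, a 2D histogram of position relative to the moving thermal
#' center, and a 2D histogram of climb rate binned by the angle from the
#' wind.
#'
#' @param trajs A trajectory tibble or a list of trajectory tibbles.
#' @param bounds Optional climb-rate bounds for the efficiency (list with
#'   `vz_optimal`, `vz_baseline`); computed from the nominal configuration
#'   when `NULL`.
#' @param xy_breaks Bin edges for the centered position histogram, m.
#' @param theta_breaks Bin edges for theta, deg.
#' @param vz_breaks Bin edges for climb rate, m/s.
#' @return An object of class `soaring_summary`: a list with `stats` (one-row
#'   tibble), `position_hist` and `theta_vz_hist` (long-format count
#'   tibbles).
#' @export
summarize_trajectories <- function(trajs, bounds = NULL,
                                   xy_breaks = seq(-100, 100, by = 10),
                                   theta_breaks = seq(-180, 180, by = 15),
                                   vz_breaks = seq(-5, 5, by = 0.5)) {
  if (is.data.frame(trajs)) trajs <- list(trajs)
  if (length(trajs) == 0 || sum(vapply(trajs, nrow, 0L)) == 0) {
    return(structure(list(
      stats = tibble::tibble(n_traj = 0L, mean_vz = NA_real_, eta = NA_real_,
                             frac_in_thermal = NA_real_,
                             mean_d_center = NA_real_, sd_d_center = NA_real_),
      position_hist = tibble::tibble(x_bin = numeric(), y_bin = numeric(),
                                     count = integer()),
      theta_vz_hist = tibble::tibble(theta_bin = numeric(), vz_bin = numeric(),
                                     count = integer())
    ), class = "soaring_summary"))
  }
  all <- dplyr::bind_rows(trajs, .id = ".traj")
  dx <- all$x - all$u * all$t
  dy <- all$y
  d <- if ("d_center" %in% names(all)) all$d_center else sqrt(dx^2 + dy^2)
  if (is.null(bounds)) bounds <- efficiency_bounds()
  mean_vz <- mean(all$vz, na.rm = TRUE)
  stats_tbl <- tibble::tibble(
    n_traj = length(trajs),
    mean_vz = mean_vz,
    eta = efficiency_eta(mean_vz, bounds),
    frac_in_thermal = mean(d <= 80),
    mean_d_center = mean(d), sd_d_center = stats::sd(d)
  )
  bin_mid <- function(v, breaks) {
    i <- findInterval(v, breaks, rightmost.closed = TRUE)
    i[i < 1 | i >= length(breaks)] <- NA
    (breaks[i] + breaks[i + 1]) / 2
  }
  pos <- tibble::tibble(x_bin = bin_mid(dx, xy_breaks),
                        y_bin = bin_mid(dy, xy_breaks)) |>
    dplyr::filter(!is.na(.data$x_bin), !is.na(.data$y_bin)) |>
    dplyr::count(.data$x_bin, .data$y_bin, name = "count")
  tv <- tibble::tibble(theta_bin = bin_mid(all$theta, theta_breaks),
                       vz_bin = bin_mid(all$vz, vz_breaks)) |>
    dplyr::filter(!is.na(.data$theta_bin), !is.na(.data$vz_bin)) |>
    dplyr::count(.data$theta_bin, .data$vz_bin, name = "count")
  structure(list(stats = stats_tbl, position_hist = pos, theta_vz_hist = tv),
            class = "soaring_summary")
}

#' @export
print.soaring_summary <- function(x, ...) {
  cat("<soaring_summary>\n")
  print(x$stats)
  invisible(x)
}

#' Invert the optimal-climb solver for thermal parameters
#'
#' Finds the thermal parameters (w*, z*) whose optimal steady-circle climb
#' rate and optimal circling radius best match observed targets (least
#' squares on the scaled 2-vector) -- the procedure used to pick study
#' thermals that match observed mean climb rates and thermalling radii.
#'
#' @param target_mean_vz Target optimal climb rate, m/s (> 0 feasible range).
#' @param target_radius Target optimal circling radius, m (> 0).
#' @param p A [glider_params()] object.
#' @param w_grid,z_grid Candidate grids for w* (m/s) and z* (m).
#' @param z Altitude for the solver, m.
#' @return A one-row tibble: `w_star`, `z_star`, the achieved `vz_optimal`
#'   and `radius`, and the least-squares `residual` (relative, 2-norm). A
#'   warning is raised when no grid point comes within 10% of both targets.
#' @export
fit_thermal_params <- function(target_mean_vz, target_radius,
                               p = glider_params(),
                               w_grid = seq(2, 8, by = 0.25),
                               z_grid = seq(1000, 3000, by = 100),
                               z = 500) {
  stopifnot(target_radius > 0)
  cand <- tidyr::expand_grid(w_star = w_grid, z_star = z_grid)
  res <- purrr::pmap_dfr(cand, function(w_star, z_star) {
    o <- optimal_climb_rate(p, thermal_params(w_star, z_star), z = z,
                            grid_step = 1)
    tibble::tibble(w_star = w_star, z_star = z_star,
                   vz_optimal = o$vz_optimal, radius = o$radius)
  })
  res$residual <- sqrt(((res$vz_optimal - target_mean_vz) / max(abs(target_mean_vz), 0.1))^2 +
                       ((res$radius - target_radius) / target_radius)^2)
  best <- res[which.min(res$residual), ]
  if (best$residual > 0.1 * sqrt(2)) {
    warning(sprintf(
      "no (w*, z*) grid point matches the targets well (best residual %.3f)",
      best$residual))
  }
  best
}
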