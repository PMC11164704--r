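# Point-mass glider dynamics with a quasi-steady aerodynamic closure.
#
# The dynamic state is (x, y, z, V, gamma, chi) where V is the air-relative
# speed, gamma the glide angle and chi the side (heading) angle of the
# air-relative velocity. Position integrates the ground velocity, i.e. the
# air-relative velocity plus the local air motion; force magnitudes are
# computed from the airspeed V. In still air the equations reduce exactly to
# the printed point-mass form. Angles are degrees at the user interface and
# radians internally.

DEG <- pi / 180

#' Glider parameters and aerodynamic coefficients
#'
#' Mass, wing area and the coefficients of the quasi-steady aerodynamic
#' closure: a linear lift curve `C_L = C_L0 + C_Lalpha * alpha[deg]`, a
#' quadratic drag polar `C_D = C_D0 + k_ind * C_L^2`, and a linear side-force
#' law `C_Y = C_Ybeta * beta[rad]`.
#'
#' Two presets are shipped. `"vulture"` (the default, also the `"nominal"`
#' study configuration) uses m = 7.75 kg and S = 0.87 m^2 with coefficients
#' calibrated so that (i) the still-air straight glide at sigma = 0, alpha =
#' 6 deg settles at -0.75 m/s and (ii) the best steady-circle climb in the
#' nominal thermal at z = 500 m is 0.72 m/s.
#'
#' @param preset `"vulture"` (alias `"nominal"`).
#' @param ... Named overrides of individual fields.
#' @return An object of class `glider_params`: fields `m` (kg), `S` (m^2),
#'   `g` (m/s^2), `rho` (kg/m^3), `C_L0`, `C_Lalpha` (1/deg), `C_D0`,
#'   `k_ind`, `C_Ybeta` (1/rad), `V_min` (m/s, stall/singularity guard).
#' @examples
#' glider_params()
#' glider_params(m = 15.5) # doubled mass
#' @export
glider_params <- function(preset = c("vulture", "nominal"), ...) {
  preset <- match.arg(preset)
  p <- list(
    m = 7.75, S = 0.87, g = 9.81, rho = 1.225,
    C_L0 = 0.30, C_Lalpha = 0.0234753905,
    C_D0 = 0.0086857488, k_ind = 0.05,
    C_Ybeta = -0.5,
    V_min = 2
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown glider parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(p$m > 0, p$S > 0, p$g > 0, p$rho > 0)
  structure(p, class = "glider_params")
}

#' Glider state constructor
#'
#' @param x,y,z Position, m.
#' @param V Air-relative speed, m/s (> 0).
#' @param gamma Glide angle, deg (negative = descending).
#' @param chi Side (heading) angle of the velocity, deg.
#' @return Named numeric state vector (angles stored in radians).
#' @export
glider_state <- function(x = 0, y = 0, z = 500, V = 15, gamma = -5, chi = 0) {
  stopifnot(V > 0)
  c(x = x, y = y, z = z, V = V, gamma = gamma * DEG, chi = chi * DEG)
}

#' Control state constructor
#'
#' @param sigma Bank angle, deg, in \[-50, 50\].
#' @param alpha Angle-of-attack, deg, in \[-30, 30\].
#' @param beta Sideslip angle, deg (0 in the nominal configuration).
#' @return Named numeric vector `c(sigma, alpha, beta)` in degrees.
#' @export
control_state <- function(sigma = 0, alpha = 6, beta = 0) {
  stopifnot(abs(sigma) <= 50, abs(alpha) <= 30)
  c(sigma = sigma, alpha = alpha, beta = beta)
}

#' Quasi-steady aerodynamic forces
#'
#' Lift, drag and side force from the airspeed and the commanded angles:
#' `L = q S C_L(alpha)`, `D = q S (C_D0 + k_ind C_L^2)`,
#' `C = q S C_Ybeta beta`, with dynamic pressure `q = rho V_air^2 / 2`.
#' The airspeed is the magnitude of the air-relative velocity.
#'
#' @param V_air Airspeed, m/s (> 0).
#' @param ctrl A [control_state()] vector (degrees).
#' @param p A [glider_params()] object.
#' @return Named vector `c(L, D, C)` in newtons.
#' @export
aerodynamic_forces <- function(V_air, ctrl, p = glider_params()) {
  if (any(V_air <= 0)) stop("non-positive airspeed: stall/singularity")
  CL <- p$C_L0 + p$C_Lalpha * ctrl[["alpha"]]
  CD <- p$C_D0 + p$k_ind * CL^2
  CY <- p$C_Ybeta * ctrl[["beta"]] * DEG
  q <- 0.5 * p$rho * p$S * V_air^2
  c(L = q * CL, D = q * CD, C = q * CY)
}

#' Equations of motion of the point-mass glider
#'
#' Six state rates: position integrates the ground velocity (air-relative
#' velocity plus local air motion); the air-relative speed and flight-path
#' angles evolve under lift, drag, side force and gravity,
#' \deqn{\dot V = -D/m - g\sin\gamma,\quad
#'       \dot\gamma = (L\cos\sigma + C\sin\sigma)/(mV) - (g/V)\cos\gamma,\quad
#'       \dot\chi = (L\sin\sigma - C\cos\sigma)/(mV\cos\gamma).}
#'
#' @param state A [glider_state()] vector.
#' @param ctrl A [control_state()] vector (degrees).
#' @param air Local air velocity `c(vx, vy, vz)`, m/s.
#' @param p A [glider_params()] object.
#' @return Named vector of the six rates.
#' @export
derivatives <- function(state, ctrl, air = c(0, 0, 0), p = glider_params()) {
  V <- state[["V"]]; gam <- state[["gamma"]]; chi <- state[["chi"]]
  if (V <= 0) stop("non-positive airspeed: stall/singularity")
  cg <- cos(gam)
  if (abs(cg) < 1e-10) stop("cos(gamma) = 0: vertical-flight singularity")
  f <- aerodynamic_forces(V, ctrl, p)
  sig <- ctrl[["sigma"]] * DEG
  c(
    x = V * cos(chi) * cg + air[[1]],
    y = V * sin(chi) * cg + air[[2]],
    z = V * sin(gam) + air[[3]],
    V = -f[["D"]] / p$m - p$g * sin(gam),
    gamma = (f[["L"]] * cos(sig) + f[["C"]] * sin(sig)) / (p$m * V) - p$g * cg / V,
    chi = (f[["L"]] * sin(sig) - f[["C"]] * cos(sig)) / (p$m * V * cg)
  )
}

#' One fixed-step integration step (classical 4th-order Runge-Kutta)
#'
#' @param state A [glider_state()] vector.
#' @param ctrl A [control_state()] vector, held constant over the step.
#' @param wind_field A function `(x, y, z, t) -> c(vx, vy, vz)`, or `NULL`
#'   for still air.
#' @param dt Step size, s (> 0). Default 0.05 s.
#' @param t Time at the start of the step, s.
#' @param p A [glider_params()] object.
#' @return The advanced state vector.
#' @export
step_glider <- function(state, ctrl, wind_field = NULL, dt = 0.05, t = 0,
                        p = glider_params()) {
  stopifnot(dt > 0)
  air <- function(s, tt) {
    if (is.null(wind_field)) c(0, 0, 0)
    else wind_field(s[["x"]], s[["y"]], s[["z"]], tt)
  }
  k1 <- derivatives(state, ctrl, air(state, t), p)
  s2 <- state + dt / 2 * k1
  k2 <- derivatives(s2, ctrl, air(s2, t + dt / 2), p)
  s3 <- state + dt / 2 * k2
  k3 <- derivatives(s3, ctrl, air(s3, t + dt / 2), p)
  s4 <- state + dt * k3
  k4 <- derivatives(s4, ctrl, air(s4, t + dt), p)
  state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Detect flight instability from a pitch history
#'
#' Flags an unstable flight when the accumulated same-direction rotation of
#' the glide angle reaches 360 degrees, or when a dynamics singularity has
#' occurred: airspeed at or below `V_min`, or |gamma| at or above 90 degrees
#' (the onset of a pitch spin in the point-mass model).
#'
#' @param gamma_history Glide-angle history, radians, sampled at the physics
#'   rate.
#' @param V Current airspeed, m/s.
#' @param p A [glider_params()] object (for `V_min`).
#' @return Logical flag.
#' @export
detect_instability <- function(gamma_history, V, p = glider_params()) {
  if (V <= p$V_min) return(TRUE)
  n <- length(gamma_history)
  if (n == 0) return(FALSE)
  if (any(abs(gamma_history) >= pi / 2 - 1e-9)) return(TRUE)
  if (n < 2) return(FALSE)
  dg <- diff(gamma_history)
  acc <- 0
  for (d in dg) {
    acc <- if (acc == 0 || sign(d) == sign(acc)) acc + d else d
    if (abs(acc) >= 2 * pi) return(TRUE)
  }
  FALSE
}

# Integrate one control interval (constant controls) at the physics step,
# monitoring crash and instability at every substep. Returns the final state,
# elapsed time within the interval, and a termination code.
integrate_interval <- function(state, ctrl, wind_field, interval = 1,
                               dt = 0.05, t0 = 0, p = glider_params()) {
  n_sub <- max(1L, round(interval / dt))
  gam_acc <- 0 # running same-direction pitch winding, rad
  for (k in seq_len(n_sub)) {
    prev_gam <- state[["gamma"]]
    state <- tryCatch(
      step_glider(state, ctrl, wind_field, dt, t0 + (k - 1) * dt, p),
      error = function(e) NULL
    )
    if (is.null(state)) {
      return(list(state = NULL, elapsed = k * dt, status = "instability"))
    }
    if (state[["z"]] <= 0) {
      state[["z"]] <- 0
      return(list(state = state, elapsed = k * dt, status = "crash"))
    }
    dg <- state[["gamma"]] - prev_gam
    gam_acc <- if (gam_acc == 0 || sign(dg) == sign(gam_acc)) gam_acc + dg else dg
    if (state[["V"]] <= p$V_min || abs(state[["gamma"]]) >= pi / 2 - 1e-9 ||
        abs(gam_acc) >= 2 * pi) {
      return(list(state = state, elapsed = k * dt, status = "instability"))
    }
  }
  list(state = state, elapsed = n_sub * dt, status = "ok")
}

# Ground velocity (air-relative + air) for a state under a wind field.
ground_velocity <- function(state, wind_field = NULL, t = 0) {
  V <- state[["V"]]; gam <- state[["gamma"]]; chi <- state[["chi"]]
  a <- if (is.null(wind_field)) c(0, 0, 0) else
    wind_field(state[["x"]], state[["y"]], state[["z"]], t)
  c(vx = V * cos(chi) * cos(gam) + a[[1]],
    vy = V * sin(chi) * cos(gam) + a[[2]],
    vz = V * sin(gam) + a[[3]])
}
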