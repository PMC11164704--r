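# Thermal updraft profile and the combined drifting-thermal + horizontal-wind
# velocity field. The updraft is a Gaussian core surrounded by a downdraft
# ring (Gedeon shape), with a Lenschow vertical amplitude profile; the thermal
# drifts downwind as a vertical "chimney" (no centerline leaning).

#' Thermal parameters
#'
#' Parameters of the convective thermal model: `w_star`, the characteristic
#' updraft amplitude (m/s), and `z_star`, the characteristic thermal altitude
#' (m). The nominal study configuration is `w_star = 5`, `z_star = 2000`.
#'
#' @param w_star Characteristic updraft amplitude, m/s. Must be > 0.
#' @param z_star Characteristic thermal altitude, m. Must be > 0.
#' @return An object of class `thermal_params`.
#' @examples
#' thermal_params()
#' @export
thermal_params <- function(w_star = 5, z_star = 2000) {
  stopifnot(is.numeric(w_star), length(w_star) == 1, w_star > 0)
  stopifnot(is.numeric(z_star), length(z_star) == 1, z_star > 0)
  structure(list(w_star = w_star, z_star = z_star), class = "thermal_params")
}

#' Horizontal wind configuration
#'
#' Uniform horizontal wind of speed `u` along +x, with optional Gaussian
#' gusts: every `gust_period` seconds the effective wind speed is resampled
#' from Normal(`u`, `gust_std`), truncated at zero.
#'
#' @param u Mean horizontal wind speed, m/s (>= 0), along +x.
#' @param gust_std Standard deviation of gust resampling, m/s (>= 0).
#' @param gust_period Gust resampling interval, s (> 0). Default 20 s.
#' @return An object of class `wind_config`.
#' @export
wind_config <- function(u = 0, gust_std = 0, gust_period = 20) {
  stopifnot(is.numeric(u), length(u) == 1, u >= 0)
  stopifnot(is.numeric(gust_std), length(gust_std) == 1, gust_std >= 0)
  stopifnot(is.numeric(gust_period), length(gust_period) == 1, gust_period > 0)
  structure(list(u = u, gust_std = gust_std, gust_period = gust_period),
            class = "wind_config")
}

#' Updraft core amplitude profile
#'
#' Vertical profile of the updraft amplitude on the thermal centerline,
#' `w* (z/z*)^(1/3) (1 - 1.1 z/z*)`. Positive below `z = z*/1.1`; the formula
#' is taken literally above that altitude (weakly negative).
#'
#' @param z Altitude, m (>= 0). Vectorised.
#' @param p A [thermal_params()] object.
#' @return Core updraft amplitude, m/s.
#' @examples
#' core_amplitude(500, thermal_params(5, 2000)) # ~2.28 m/s
#' @export
core_amplitude <- function(z, p = thermal_params()) {
  stopifnot(inherits(p, "thermal_params"), all(z >= 0))
  zr <- z / p$z_star
  p$w_star * zr^(1 / 3) * (1 - 1.1 * zr)
}

#' Thermal radius profile
#'
#' Radius of the updraft core as a function of altitude,
#' `0.08 (z/z*)^(1/3) (1 - z/(4 z*)) z*`.
#'
#' @inheritParams core_amplitude
#' @return Thermal radius, m.
#' @examples
#' thermal_radius(500, thermal_params(5, 2000)) # ~94.5 m
#' @export
thermal_radius <- function(z, p = thermal_params()) {
  stopifnot(inherits(p, "thermal_params"), all(z >= 0))
  zr <- z / p$z_star
  0.08 * zr^(1 / 3) * (1 - zr / 4) * p$z_star
}

#' Updraft velocity at radial distance r
#'
#' Radial updraft profile `w_core(z) exp(-(r/R)^2) (1 - (r/R)^2)`: a central
#' rising core surrounded by a ring of sinking air for `r > R(z)`.
#'
#' @param r Radial distance from the thermal center, m (>= 0). Vectorised.
#' @param z Altitude, m (> 0).
#' @param p A [thermal_params()] object.
#' @return Vertical air velocity, m/s.
#' @examples
#' updraft(0, 500)                  # core amplitude
#' updraft(thermal_radius(500), 500) # exactly zero
#' @export
updraft <- function(r, z, p = thermal_params()) {
  stopifnot(all(r >= 0), all(z > 0))
  rr <- (r / thermal_radius(z, p))^2
  core_amplitude(z, p) * exp(-rr) * (1 - rr)
}

#' Local air velocity of the drifting-thermal wind field
#'
#' Combined atmospheric model: uniform horizontal wind `(u, 0)` plus the
#' updraft of a thermal whose center, at `(0, 0)` at `t = 0`, drifts downwind
#' at speed `u`. The vertical component is evaluated at the drift-corrected
#' radius `r(t) = sqrt((x - u t)^2 + y^2)`. Pass `u_effective` to evaluate the
#' field under a gust-modified wind speed while the thermal keeps drifting at
#' the mean wind (the core advects with the mean flow).
#'
#' @param x,y,z Position, m (`z > 0`).
#' @param t Time since episode start, s.
#' @param w A [wind_config()] object.
#' @param p A [thermal_params()] object.
#' @param u_effective Optional instantaneous (gust) wind speed, m/s; defaults
#'   to `w$u`.
#' @return A named numeric vector `c(vx, vy, vz)`, m/s.
#' @export
wind_vector <- function(x, y, z, t, w = wind_config(), p = thermal_params(),
                        u_effective = NULL) {
  u_now <- if (is.null(u_effective)) w$u else u_effective
  r <- sqrt((x - w$u * t)^2 + y^2)
  # below ground (transient integrator stages while a crash terminates the
  # episode) the updraft is taken as zero
  vz <- if (z > 0) updraft(r, z, p) else 0
  c(vx = u_now, vy = 0, vz = vz)
}

#' Position of the drifting thermal center
#'
#' @param t Time, s.
#' @param w A [wind_config()] object.
#' @return A length-2 vector `c(x, y)`, m.
#' @export
thermal_center <- function(t, w = wind_config()) {
  c(w$u * t, 0)
}

# Draw one gust value: Normal(u, gust_std) truncated at zero.
sample_gust <- function(w) {
  if (w$gust_std <= 0) return(w$u)
  max(0, stats::rnorm(1, mean = w$u, sd = w$gust_std))
}
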