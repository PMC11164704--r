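# Kinematic estimators for 1 Hz soaring tracks (simulator output or
# bird-style GPS trajectories): bank angle from centripetal acceleration,
# wind from the mean planar drift, local thermalling diameter from
# interlacing triangles of with-wind / against-wind crossing points, and
# selection of consistent thermalling segments.

check_uniform_1hz <- function(traj) {
  stopifnot(all(c("t", "x", "y") %in% names(traj)), nrow(traj) >= 3)
  dt <- diff(traj$t)
  if (any(dt <= 0)) stop("trajectory time must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-6) stop("estimators require uniform sampling")
  dt[1]
}

#' Estimate the mean bank angle of a circling trajectory
#'
#' For a banked, non-slipping turn the radial force balance gives
#' `tan(sigma) = a_r / g` (drag and the small vertical acceleration
#' neglected). The radial acceleration is obtained from second differences
#' of the planar position; at each interior sample the bank is
#' `atan(a_r / g)` where `a_r` is the component of the acceleration
#' perpendicular to the (central-difference) velocity, and the estimate is
#' the trajectory mean.
#'
#' @param traj Trajectory tibble with columns `t`, `x`, `y` at uniform 1 Hz
#'   (any uniform rate is accepted).
#' @param g Gravitational acceleration, m/s^2.
#' @return Mean bank angle estimate, degrees (attribute `sigma_t` holds the
#'   per-step series). Straight tracks return ~0 with a `low_curvature`
#'   attribute set.
#' @examples
#' circ <- tibble::tibble(t = 0:60,
#'                        x = 30 * cos(0.5 * 0:60), y = 30 * sin(0.5 * 0:60))
#' estimate_bank(circ) # uniform circle, V = 15 m/s, r = 30 m
#' @export
estimate_bank <- function(traj, g = 9.81) {
  dt <- check_uniform_1hz(traj)
  n <- nrow(traj)
  x <- traj$x; y <- traj$y
  i <- 2:(n - 1)
  vx <- (x[i + 1] - x[i - 1]) / (2 * dt)
  vy <- (y[i + 1] - y[i - 1]) / (2 * dt)
  ax <- (x[i + 1] - 2 * x[i] + x[i - 1]) / dt^2
  ay <- (y[i + 1] - 2 * y[i] + y[i - 1]) / dt^2
  v <- sqrt(vx^2 + vy^2)
  ok <- v > 1e-9
  a_r <- abs(vx * ay - vy * ax)[ok] / v[ok] # |v x a| / |v|: centripetal part
  sigma_t <- atan(a_r / g) / DEG
  out <- mean(sigma_t)
  attr(out, "sigma_t") <- sigma_t
  if (mean(a_r) < 0.1 * g * tan(2 * DEG)) {
    attr(out, "low_curvature") <- TRUE
    warning("low-curvature trajectory: bank estimate ~0 is not meaningful")
  }
  out
}

#' Estimate the horizontal wind from a thermalling trajectory
#'
#' Mean planar velocity over the entire thermalling trajectory: over closed
#' circling loops the circular component cancels and the mean equals the
#' drift, i.e. the horizontal wind. To suppress the partial-loop bias the
#' average is taken over the largest whole number of circles (the cumulative
#' heading trimmed to a multiple of 360 deg, end point interpolated).
#' Trajectories covering fewer than two full turns get a `short_track`
#' attribute and a bias warning.
#'
#' @param traj Trajectory tibble with `t`, `x`, `y` at uniform sampling.
#' @return Estimated wind 2-vector `c(wx, wy)`, m/s.
#' @export
estimate_wind <- function(traj) {
  dt <- check_uniform_1hz(traj)
  n <- nrow(traj)
  vx <- diff(traj$x) / dt; vy <- diff(traj$y) / dt
  dh <- diff(atan2(vy, vx))
  dh <- (dh + pi) %% (2 * pi) - pi
  cum <- c(0, cumsum(dh)) # turn accumulated at chord i relative to chord 1
  n_turns <- abs(cum[length(cum)]) / (2 * pi)
  short <- n_turns < 2
  # chord i joins points i and i+1; its natural anchor is the midpoint
  mid_x <- (traj$x[-n] + traj$x[-1]) / 2
  mid_y <- (traj$y[-n] + traj$y[-1]) / 2
  mid_t <- (traj$t[-n] + traj$t[-1]) / 2
  t1 <- mid_t[1]; p1 <- c(mid_x[1], mid_y[1])
  k <- trunc(cum[length(cum)] / (2 * pi))
  if (k != 0) {
    target <- k * 2 * pi
    # last chord index where cum crosses k full turns; interpolate between
    # adjacent chord midpoints
    j <- max(which(
      (cum[-length(cum)] - target) * (cum[-1] - target) <= 0))
    frac <- if (cum[j + 1] == cum[j]) 0 else
      (target - cum[j]) / (cum[j + 1] - cum[j])
    t2 <- mid_t[j] + frac * (mid_t[j + 1] - mid_t[j])
    p2 <- c(mid_x[j] + frac * (mid_x[j + 1] - mid_x[j]),
            mid_y[j] + frac * (mid_y[j + 1] - mid_y[j]))
  } else {
    t2 <- mid_t[n - 1]; p2 <- c(mid_x[n - 1], mid_y[n - 1])
  }
  w <- c(wx = p2[1] - p1[1], wy = p2[2] - p1[2]) / (t2 - t1)
  if (short) {
    attr(w, "short_track") <- TRUE
    warning("trajectory covers fewer than two full circles: wind estimate may be biased")
  }
  w
}

# theta series (deg) for a trajectory from planar finite differences,
# given a wind direction; rotation sense from the net turning sign.
trajectory_theta <- function(traj, wind_dir = c(1, 0)) {
  dt <- check_uniform_1hz(traj)
  n <- nrow(traj)
  i <- 2:(n - 1)
  vx <- (traj$x[i + 1] - traj$x[i - 1]) / (2 * dt)
  vy <- (traj$y[i + 1] - traj$y[i - 1]) / (2 * dt)
  dh <- diff(atan2(vy, vx))
  dh <- (dh + pi) %% (2 * pi) - pi
  sense <- if (sum(dh) >= 0) "CCW" else "CW"
  th <- vapply(seq_along(vx), function(k) {
    if (vx[k]^2 + vy[k]^2 < 1e-12) return(NA_real_)
    compute_theta(c(vx[k], vy[k]), wind_dir, sense)
  }, numeric(1))
  tibble::tibble(t = traj$t[i], theta = th, sense = sense)
}

# Unwrap a degree series to a continuous cumulative angle.
unwrap_deg <- function(th) {
  d <- diff(th)
  d <- (d + 180) %% 360 - 180
  cumsum(c(th[1], d))
}

#' Local thermalling diameter from interlacing crossing triangles
#'
#' Projects the track to the xy plane, finds the crossings of theta through
#' +/-180 deg (type A: flying with the wind) and through 0 (type B: flying
#' against the wind), time-sorts them, and forms interlacing ABA / BAB
#' triangles of consecutive crossing points. Each triangle contributes one
#' local-diameter estimate: the altitude from the B vertex in an ABA
#' triangle, and from the A vertex in a BAB triangle. Crossing positions are
#' linearly interpolated to sub-second resolution.
#'
#' @param traj Trajectory tibble (`t`, `x`, `y` at uniform sampling).
#' @param wind_dir Unit 2-vector of the wind direction; estimated via
#'   [estimate_wind()] when `NULL`.
#' @return A tibble with one row per triangle: `t` (time of the apex
#'   vertex), `type` (`"ABA"`/`"BAB"`), `diameter` (m). Zero rows (with a
#'   `reason` attribute) when fewer than three alternating crossings exist.
#' @export
thermalling_diameter <- function(traj, wind_dir = NULL) {
  if (is.null(wind_dir)) {
    w <- suppressWarnings(estimate_wind(traj))
    if (sqrt(sum(w^2)) < 1e-9) stop("wind direction undefined (no drift); supply wind_dir")
    wind_dir <- w / sqrt(sum(w^2))
  }
  th <- trajectory_theta(traj, wind_dir)
  keep <- !is.na(th$theta)
  thc <- unwrap_deg(th$theta[keep])
  tt <- th$t[keep]
  # crossing levels: multiples of 180; even multiples of 180 (0 mod 360) are
  # type B (against wind), odd multiples are type A (with wind)
  lev_lo <- ceiling(min(thc) / 180); lev_hi <- floor(max(thc) / 180)
  if (lev_hi < lev_lo) {
    out <- tibble::tibble(t = numeric(), type = character(), diameter = numeric())
    attr(out, "reason") <- "no theta crossings"
    return(out)
  }
  cross <- purrr::map_dfr(lev_lo:lev_hi, function(m) {
    lvl <- 180 * m
    s <- thc - lvl
    j <- which(s[-length(s)] * s[-1] <= 0 & s[-length(s)] != s[-1])
    if (!length(j)) return(NULL)
    frac <- -s[j] / (s[j + 1] - s[j])
    tibble::tibble(
      t = tt[j] + frac * (tt[j + 1] - tt[j]),
      type = if (m %% 2 == 0) "B" else "A"
    )
  })
  if (nrow(cross) < 3) {
    out <- tibble::tibble(t = numeric(), type = character(), diameter = numeric())
    attr(out, "reason") <- "fewer than 3 crossing points"
    return(out)
  }
  cross <- dplyr::arrange(cross, .data$t)
  # interpolated positions at the crossing times
  cross$x <- stats::approx(traj$t, traj$x, cross$t)$y
  cross$y <- stats::approx(traj$t, traj$y, cross$t)$y
  tri <- purrr::map_dfr(seq_len(nrow(cross) - 2L), function(k) {
    ty <- cross$type[k:(k + 2)]
    if (!(all(ty == c("A", "B", "A")) || all(ty == c("B", "A", "B")))) return(NULL)
    p1 <- c(cross$x[k], cross$y[k])
    p2 <- c(cross$x[k + 1], cross$y[k + 1])
    p3 <- c(cross$x[k + 2], cross$y[k + 2])
    # altitude from the apex, computed as apex-to-base-segment distance:
    # identical to the triangle altitude when the foot falls inside the
    # base, and well-conditioned in the near-degenerate small-drift limit
    # where the two base points almost coincide (tends to the diameter).
    base <- p3 - p1
    bl2 <- sum(base^2)
    tt <- if (bl2 < 1e-12) 0 else
      min(1, max(0, sum((p2 - p1) * base) / bl2))
    foot <- p1 + tt * base
    alt <- sqrt(sum((p2 - foot)^2))
    tibble::tibble(t = cross$t[k + 1],
                   type = paste(ty, collapse = ""), diameter = alt)
  })
  if (nrow(tri) == 0) attr(tri, "reason") <- "no alternating ABA/BAB triples"
  tri
}

#' Validate the bank-angle estimator on scripted circling fixtures
#'
#' Generates seeded constant-control circling trajectories with known bank
#' angle and wind, subsamples them to 1 Hz positions, runs [estimate_bank()]
#' on each, and reports per-trajectory relative errors. The study-grade
#' validation uses 20 fixtures with banks spanning 20-45 deg and winds
#' 0-5 m/s over 200 s flights.
#'
#' @param seeds Integer seeds, one fixture per seed.
#' @param sigma_range Range of true bank angles, deg.
#' @param u_range Range of horizontal wind speeds, m/s.
#' @param duration Fixture duration, s.
#' @param gp A [glider_params()] object.
#' @return A tibble: `seed`, `sigma_true`, `u`, `sigma_hat`, `rel_err`; the
#'   mean relative error (as a fraction) is attached as attribute
#'   `mean_rel_err`.
#' @export
validate_bank_estimator <- function(seeds = 1:20, sigma_range = c(20, 45),
                                    u_range = c(0, 5), duration = 200,
                                    gp = glider_params()) {
  res <- purrr::map_dfr(seeds, function(s) {
    set.seed(s)
    sigma_true <- stats::runif(1, sigma_range[1], sigma_range[2])
    u <- stats::runif(1, u_range[1], u_range[2])
    tr <- scripted_circler(sigma_true, wind = wind_config(u),
                           duration = duration, seed = s, gp = gp)
    sh <- as.numeric(suppressWarnings(estimate_bank(tr, g = gp$g)))
    tibble::tibble(seed = s, sigma_true = sigma_true, u = u, sigma_hat = sh,
                   rel_err = abs(sh - sigma_true) / sigma_true)
  })
  attr(res, "mean_rel_err") <- mean(res$rel_err)
  res
}

#' Select consistent thermalling segments
#'
#' Returns maximal sub-segments with consistent circling: the heading
#' progresses monotonically (at most 10% retrograde samples within the
#' segment), the net rotation is at least `min_turns` full turns, and the
#' duration is at least `min_duration` seconds.
#'
#' @param traj Trajectory tibble (`t`, `x`, `y` at uniform sampling).
#' @param min_duration Minimum segment duration, s. Default 100.
#' @param min_turns Minimum number of net full turns. Default 2.
#' @param max_retrograde Maximum tolerated fraction of retrograde heading
#'   steps. Default 0.1.
#' @param smooth_window Heading-rate smoothing window, samples. Default 5.
#' @return A tibble with one row per segment: `start`, `end` (s), `duration`
#'   (s), `n_turns`, `sense`.
#' @export
select_thermalling_segments <- function(traj, min_duration = 100,
                                        min_turns = 2, max_retrograde = 0.1,
                                        smooth_window = 5) {
  dt <- check_uniform_1hz(traj)
  vx <- diff(traj$x) / dt; vy <- diff(traj$y) / dt
  dh <- diff(atan2(vy, vx))
  dh <- (dh + pi) %% (2 * pi) - pi # heading increments at t[2..n-1]
  if (!length(dh)) return(empty_segments())
  sm <- stats::filter(dh, rep(1 / smooth_window, smooth_window), sides = 2)
  sm[is.na(sm)] <- dh[is.na(sm)]
  turning <- abs(sm) > (2 * pi / 600) # at least one turn per 10 min
  s <- sign(sm) * turning
  # maximal runs of a consistent dominant sense
  runs <- rle(as.numeric(s))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- purrr::pmap_dfr(
    list(starts[runs$values != 0], ends[runs$values != 0],
         runs$values[runs$values != 0]),
    function(a, b, sense) {
      idx <- a:b
      retro <- mean(sign(dh[idx]) != sense & dh[idx] != 0)
      net <- abs(sum(dh[idx])) / (2 * pi)
      dur <- (b - a + 1) * dt
      if (dur >= min_duration && net >= min_turns && retro <= max_retrograde) {
        tibble::tibble(start = traj$t[a + 1], end = traj$t[b + 1],
                       duration = dur, n_turns = net,
                       sense = if (sense > 0) "CCW" else "CW")
      } else NULL
    })
  if (nrow(segs) == 0) empty_segments() else segs
}

empty_segments <- function() {
  tibble::tibble(start = numeric(), end = numeric(), duration = numeric(),
                 n_turns = numeric(), sense = character())
}
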