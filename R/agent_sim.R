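# Closed-loop behavioural test: an agent follows a predefined outward route
# (standing in for recorded desert-ant foraging paths), integrating a home
# vector from its compass heading estimates, then homes along the vector.
# The path-integration stage is a population-code home-vector integrator
# driven by the 8 sinusoidally tuned TCL compass neurons (the same input
# interface an anatomical central-complex model would consume). Terrain
# tilts the sensor; the ephemeris clock advances with distance walked.

#' Generate a random terrain
#'
#' Smooth Gaussian random height field over a square arena. Heights are
#' drawn i.i.d. normal on a grid and smoothed with a Gaussian kernel; the
#' field is then rescaled so its standard deviation equals
#' `altitude_sd` metres. The local tilt of an agent standing at a point is
#' the deviation of the surface normal from vertical.
#'
#' @param size arena side length in metres (arena spans `[0, size]^2`).
#' @param res grid resolution in metres.
#' @param altitude_sd standard deviation of the height field in metres
#'   (default 0.8; with the default smoothing this yields maximum tilts
#'   close to 47 degrees on a 20 m arena).
#' @param smooth_length Gaussian smoothing length in metres. Controls the
#'   horizontal correlation scale and hence the slopes: smaller values give
#'   steeper terrain for the same altitude variance.
#' @param seed integer seed.
#' @return an object of class `terrain`: list with the height matrix `h`,
#'   grids `x`, `y`, gradients `hx`, `hy`, `delta_max` (maximum tilt in
#'   degrees over the grid) and the parameters.
#' @export
generate_terrain <- function(size = 20, res = 0.25, altitude_sd = 0.8,
                             smooth_length = 1.7, seed = 1) {
  stopifnot(altitude_sd >= 0, size > 0, res > 0)
  x <- seq(0, size, by = res)
  nx <- length(x)
  if (altitude_sd == 0) {
    h <- matrix(0, nx, nx)
  } else {
    z <- with_seed(seed, matrix(stats::rnorm(nx * nx), nx, nx))
    # FFT-based circular convolution with a Gaussian kernel
    ii <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) * res
    k1 <- exp(-0.5 * (ii / smooth_length)^2)
    K <- outer(k1, k1)
    h <- Re(stats::fft(stats::fft(z) * stats::fft(K / sum(K)),
                       inverse = TRUE)) / (nx * nx)
    h <- h / stats::sd(h) * altitude_sd
  }
  hx <- matrix(0, nx, nx); hy <- matrix(0, nx, nx)
  hx[, 2:(nx - 1)] <- (h[, 3:nx] - h[, 1:(nx - 2)]) / (2 * res)
  hy[2:(nx - 1), ] <- (h[3:nx, ] - h[1:(nx - 2), ]) / (2 * res)
  slope <- sqrt(hx^2 + hy^2)
  structure(list(h = h, x = x, y = x, hx = hx, hy = hy, res = res,
                 size = size, altitude_sd = altitude_sd,
                 smooth_length = smooth_length,
                 delta_max = max(atan(slope)) / .D2R),
            class = "terrain")
}

#' @export
print.terrain <- function(x, ...) {
  cat(sprintf("<terrain> %g x %g m, altitude sd %g m, max tilt %.1f deg\n",
              x$size, x$size, x$altitude_sd, x$delta_max))
  invisible(x)
}

#' Tilt of the terrain at a position
#'
#' @param terrain a [generate_terrain()] field.
#' @param x,y position in metres (clamped to the arena).
#' @return list with `delta` (tilt magnitude, degrees), `theta_t`
#'   (`90 - delta`) and `phi_t` (uphill azimuth, degrees clockwise from
#'   north; the surface normal leans towards `phi_t + 180`). Flat terrain
#'   gives `delta = 0`.
#' @export
terrain_tilt <- function(terrain, x, y) {
  i <- pmin(pmax(round(y / terrain$res) + 1, 1), length(terrain$y))
  j <- pmin(pmax(round(x / terrain$res) + 1, 1), length(terrain$x))
  gx <- terrain$hx[cbind(i, j)]
  gy <- terrain$hy[cbind(i, j)]
  delta <- atan(sqrt(gx^2 + gy^2)) / .D2R
  # the sensor zenith leans downhill: normal ~ (-hx, -hy, 1)
  phi_t <- wrap360(atan2d(-gx, -gy))
  list(delta = delta, theta_t = 90 - delta, phi_t = phi_t)
}

#' Generate a synthetic outward foraging route
#'
#' Correlated random walk from the nest (origin) towards a feeder,
#' emulating the tortuous outward paths of desert-ant foraging: each step
#' heads towards the feeder with added wrapped-normal heading noise.
#'
#' @param feeder_dist nest-to-feeder distance in metres (default 7 m; long
#'   runs scale the arena and route by a factor, e.g. 100 for ~700 m).
#' @param step step length in metres.
#' @param tortuosity heading noise as a fraction: the standard deviation of
#'   the per-step heading deviation is `tortuosity * 90` degrees. 0 gives a
#'   straight line to the feeder.
#' @param feeder_azimuth azimuth of the feeder from the nest in degrees.
#' @param seed integer seed.
#' @return an object of class `route`: data frame with `direction`
#'   (degrees) and `distance` (metres) per step, plus attributes `feeder`
#'   (coordinates) and `length` (total path length).
#' @export
generate_route <- function(feeder_dist = 7, step = 0.3, tortuosity = 0.3,
                           feeder_azimuth = 45, seed = 1) {
  stopifnot(feeder_dist > 0, step > 0, tortuosity >= 0)
  feeder <- feeder_dist * c(sind(feeder_azimuth), cosd(feeder_azimuth))
  pos <- c(0, 0)
  dirs <- dists <- c()
  max_steps <- ceiling(feeder_dist / step * 20)
  noise <- if (tortuosity > 0)
    with_seed(seed, stats::rnorm(max_steps, 0, tortuosity * 90)) else
    rep(0, max_steps)
  for (k in seq_len(max_steps)) {
    to_feeder <- feeder - pos
    d <- sqrt(sum(to_feeder^2))
    if (d < step) break
    head_k <- wrap360(atan2d(to_feeder[1], to_feeder[2]) + noise[k])
    pos <- pos + step * c(sind(head_k), cosd(head_k))
    dirs <- c(dirs, head_k); dists <- c(dists, step)
  }
  out <- data.frame(direction = dirs, distance = dists)
  attr(out, "feeder") <- feeder
  attr(out, "length") <- sum(dists)
  class(out) <- c("route", "data.frame")
  out
}

# Home-vector integrator fed by the TCL population: the heading estimate is
# decoded from the 8 sinusoidally tuned compass neurons and integrated with
# the walked distance. Returns the heading estimate in the compass reference
# frame (an arbitrary but consistent world-stable frame).
tcl_heading <- function(est) {
  wrap360(-est$tcl_azimuth)
}

#' Run one closed-loop foraging + homing trial
#'
#' The agent walks the outward route (in world coordinates), sensing the
#' sky at every step to estimate its heading via the compass, and
#' accumulates a home vector from (estimated heading, distance) in the
#' compass reference frame. At the feeder it turns home: at each inward
#' step it steers so that the compass heading estimate matches the home
#' vector direction (bounded turn rate), until the home vector is consumed,
#' then performs a systematic spiral-like search. The simulated clock
#' advances with distance walked; the sun moves accordingly (and the TCL
#' preferred angles rotate with it when time compensation is on).
#'
#' @param route a [generate_route()].
#' @param terrain optional [generate_terrain()]; `NULL` for flat ground.
#'   The route is walked in arena coordinates with the nest at the arena
#'   centre.
#' @param compass a [build_compass()]; `"oracle"` uses ground-truth heading
#'   (perfect compass stub).
#' @param array a [build_dra()] sensor array.
#' @param eta disturbance fraction.
#' @param time_comp logical; enable the ephemeris rotation of the TCL
#'   preferred angles (overrides `compass$time_comp`).
#' @param sky_cfg a [sky_config()]; sun position is computed from its
#'   ephemeris fields at the simulated clock time.
#' @param start_time local clock time in hours at departure (default 10).
#' @param speed walking speed in m/s.
#' @param scale spatial scale factor applied to the route (e.g. 100 for the
#'   long-run experiment).
#' @param max_turn maximum inward turn per step in degrees.
#' @param search_radius home-vector magnitude (metres) below which the
#'   agent switches to nest search.
#' @param seed master seed (disturbance masks).
#' @return an object of class `trial_result`: list with `trajectory` (data
#'   frame: `t` hours, `x`, `y`, `heading_true`, `heading_est`, `tau`,
#'   `delta`, `phase` in outward/inward/search), `nest` coordinates,
#'   `endpoint_error` (distance from nest at the end of the inward phase,
#'   metres), `arrived` (logical: came within `search_radius` of the nest),
#'   and `metrics` from [tortuosity()].
#' @export
run_trial <- function(route, terrain = NULL, compass = build_compass(),
                      array = build_dra(), eta = 0, time_comp = FALSE,
                      sky_cfg = sky_config(), start_time = 10, speed = 0.3,
                      scale = 1, max_turn = 30, search_radius = 0.5,
                      seed = 1) {
  oracle <- identical(compass, "oracle")
  if (!oracle && is.null(compass$offset))
    compass <- calibrate_compass(compass, array, sky_cfg$d_max)
  nest <- if (is.null(terrain)) c(0, 0) else rep(terrain$size / 2, 2)
  search_radius <- search_radius * scale

  clock <- start_time
  sun <- solar_position(sky_cfg$date, clock, sky_cfg$latitude,
                        sky_cfg$longitude, sky_cfg$tz)
  tcl_prefs <- if (!oracle) compass$tcl_prefs else NULL

  pos <- nest
  hv <- c(0, 0)        # home vector in the compass reference frame
  step_i <- 0L
  traj <- list()
  # one failure mask per trial: the disturbance stands in for clouds or
  # occlusion, which persist over a foraging run; the resulting systematic
  # compass bias largely cancels between the outward and inward legs
  trial_mask <- failure_mask(array$n, eta, derive_seed(seed, "trial-mask"))
  sense_heading <- function(heading, pos, step_i) {
    if (oracle) return(list(est = heading, tau = Inf, delta = 0))
    tl <- if (is.null(terrain)) list(theta_t = 90, phi_t = 0, delta = 0)
          else terrain_tilt(terrain, pos[1], pos[2])
    posed <- pose_sensor(array, tl$theta_t, tl$phi_t, yaw = heading)
    sky <- sky_state(sun, sky_cfg)
    cmp2 <- compass
    cmp2$tcl_prefs <- tcl_prefs
    pol <- sense(sky, posed, eta = 0)
    pol$r_pol[trial_mask] <- 0
    pol$failed <- trial_mask
    gate <- array_gate(cmp2, posed)
    rs <- sol_response(pol, posed, cmp2, gate)
    dec <- decode_population(rs)
    rt <- tcl_response(rs, cmp2)
    dect <- decode_population(rt)
    est <- list(tau = dec$tau,
                tcl_azimuth = wrap360(dect$angle + cmp2$offset))
    list(est = tcl_heading(est), tau = est$tau, delta = tl$delta)
  }
  advance_clock <- function(dist) {
    clock <<- clock + dist / speed / 3600
    sun <<- solar_position(sky_cfg$date, clock, sky_cfg$latitude,
                           sky_cfg$longitude, sky_cfg$tz)
  }
  record <- function(phase, heading, sn) {
    traj[[length(traj) + 1L]] <<- data.frame(
      t = clock, x = pos[1], y = pos[2], heading_true = heading,
      heading_est = sn$est, tau = if (is.finite(sn$tau)) sn$tau else NA,
      delta = sn$delta, phase = phase)
  }

  # outward: follow the route
  for (k in seq_len(nrow(route))) {
    step_i <- step_i + 1L
    heading <- route$direction[k]
    dist <- route$distance[k] * scale
    sn <- sense_heading(heading, pos, step_i)
    if (!oracle && time_comp)
      tcl_prefs <- update_tcl_prefs(tcl_prefs, sn$tau, dist / speed / 3600)
    hv <- hv - dist * c(sind(sn$est), cosd(sn$est))
    pos <- pos + dist * c(sind(heading), cosd(heading))
    advance_clock(dist)
    record("outward", heading, sn)
  }

  # inward: steer along the home vector until it is consumed
  step_len <- mean(route$distance) * scale
  heading <- wrap360(atan2d(hv[1], hv[2]))   # initial guess in est frame
  max_inward <- ceiling(4 * attr(route, "length") * scale / step_len)
  inward_travel <- 0
  for (k in seq_len(max_inward)) {
    step_i <- step_i + 1L
    if (sqrt(sum(hv^2)) < search_radius) break
    desired <- wrap360(atan2d(hv[1], hv[2]))
    sn <- sense_heading(heading, pos, step_i)
    turn <- pmin(max_turn, pmax(-max_turn, wrap180(desired - sn$est)))
    heading <- wrap360(heading + turn)
    sn$est <- wrap360(sn$est + turn)   # compass reading is linear in yaw
    if (!oracle && time_comp)
      tcl_prefs <- update_tcl_prefs(tcl_prefs, sn$tau,
                                    step_len / speed / 3600)
    hv <- hv - step_len * c(sind(sn$est), cosd(sn$est))
    pos <- pos + step_len * c(sind(heading), cosd(heading))
    advance_clock(step_len)
    record("inward", heading, sn)
    inward_travel <- inward_travel + step_len
  }

  endpoint_error <- sqrt(sum((pos - nest)^2))

  # systematic search: an Archimedean spiral around the point where the
  # home vector ran out, with loop spacing equal to the search radius, for
  # a travel budget of 2.5x the nest-feeder distance in total
  min_dist <- endpoint_error
  centre <- pos
  budget <- max(0, 1.5 * sqrt(sum((attr(route, "feeder") * scale)^2)) -
                  inward_travel)
  if (budget > 0 && endpoint_error > search_radius) {
    s_travel <- 0; ang <- 0
    while (s_travel < budget) {
      r <- search_radius * ang / (2 * pi) + 1e-6
      dang <- step_len / r
      ang <- ang + min(dang, pi / 4)
      r <- search_radius * ang / (2 * pi)
      newpos <- centre + r * c(sin(ang), cos(ang))
      s_travel <- s_travel + sqrt(sum((newpos - pos)^2))
      pos <- newpos
      advance_clock(step_len)
      d_nest <- sqrt(sum((pos - nest)^2))
      min_dist <- min(min_dist, d_nest)
      traj[[length(traj) + 1L]] <- data.frame(
        t = clock, x = pos[1], y = pos[2], heading_true = NA,
        heading_est = NA, tau = NA, delta = 0, phase = "search")
      if (d_nest <= search_radius) break
    }
    inward_travel <- inward_travel + s_travel
  }

  trajectory <- do.call(rbind, traj)
  structure(list(trajectory = trajectory, nest = nest,
                 endpoint_error = endpoint_error,
                 min_nest_distance = min_dist,
                 arrived = min_dist <= search_radius,
                 inward_travel = inward_travel,
                 metrics = tortuosity(trajectory, nest)),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> endpoint error %.2f m, closest approach %.2f m (%s), inward travel %.1f m, final tortuosity %.3f\n",
              x$endpoint_error, x$min_nest_distance,
              if (x$arrived) "arrived" else "missed",
              x$inward_travel, x$metrics$final))
  invisible(x)
}

#' Tortuosity of the inward route
#'
#' `tau(t) = L / C` where `L` is the current distance from the nest and `C`
#' the inward distance travelled so far. A straight, correct inbound path
#' drives `tau` towards 0 at arrival; circling at constant distance decays
#' only hyperbolically.
#'
#' @param trajectory a trial trajectory data frame (needs columns `x`, `y`,
#'   `phase`).
#' @param nest nest coordinates.
#' @return list with `curve` (data frame `C`, `L`, `tau`) and `final` (the
#'   last tortuosity value; `NA` if no inward travel).
#' @export
tortuosity <- function(trajectory, nest = c(0, 0)) {
  inw <- trajectory[trajectory$phase != "outward", , drop = FALSE]
  if (nrow(inw) < 2) return(list(curve = NULL, final = NA_real_))
  dx <- diff(inw$x); dy <- diff(inw$y)
  C <- cumsum(sqrt(dx^2 + dy^2))
  L <- sqrt((inw$x[-1] - nest[1])^2 + (inw$y[-1] - nest[2])^2)
  curve <- data.frame(C = C, L = L, tau = L / C)
  list(curve = curve, final = curve$tau[nrow(curve)])
}
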