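# Population compass: POL responses are combined by a sum-of-sinusoids into
# an 8-neuron solar layer (SOL) whose fundamental Fourier component encodes
# the solar azimuth (phase) and a confidence (amplitude). A Gaussian ring
# gating function reweights units under tilt, and a true-compass layer (TCL)
# with slowly rotating preferred angles compensates for solar motion using
# an ephemeris rate inferred from the confidence.

#' Build a compass model
#'
#' @param n_sol number of solar-layer neurons (default 8).
#' @param n_tcl number of true-compass-layer neurons (default 8, matching
#'   the eight compass columns of the insect protocerebral bridge).
#' @param gating logical; apply the tilt gating ring (default `TRUE`).
#' @param theta_g gating ring radius in degrees from the (tilted) zenith
#'   (default 40).
#' @param sigma_g gating ring width in degrees (default 13).
#' @param time_comp logical; enable the confidence-driven rotation of TCL
#'   preferred angles (default `FALSE`; the agent simulation switches it on).
#' @return an object of class `pol_compass` with preferred angles
#'   `sol_prefs` and `tcl_prefs` (degrees, `xi * 360 / n`), the gating
#'   parameters, and a decoder calibration `offset` (set by
#'   [calibrate_compass()], or lazily on first use).
#' @export
build_compass <- function(n_sol = 8, n_tcl = 8, gating = TRUE,
                          theta_g = 40, sigma_g = 13, time_comp = FALSE) {
  stopifnot(n_sol >= 2, n_tcl >= 2, theta_g >= 0, theta_g <= 90, sigma_g > 0)
  structure(list(
    n_sol = n_sol, n_tcl = n_tcl,
    sol_prefs = wrap360(seq_len(n_sol) * 360 / n_sol),
    tcl_prefs = wrap360(seq_len(n_tcl) * 360 / n_tcl),
    gating = gating, theta_g = theta_g, sigma_g = sigma_g,
    time_comp = time_comp, offset = NULL),
    class = "pol_compass")
}

#' @export
print.pol_compass <- function(x, ...) {
  cat(sprintf("<pol_compass> n_sol = %d, n_tcl = %d, gating %s (theta_g = %g, sigma_g = %g), time compensation %s\n",
              x$n_sol, x$n_tcl, if (x$gating) "on" else "off",
              x$theta_g, x$sigma_g, if (x$time_comp) "on" else "off"))
  invisible(x)
}

#' Tilt gating weight of a sensor unit
#'
#' Gaussian ring weighting centred `theta_g` degrees from the tilted zenith:
#' `g = exp(-u^2 / (2 sigma^2))` with
#' `u = cos(theta_g + theta_j) sin(theta_t) - sin(theta_g + theta_j) cos(theta_t) cos(phi_t - phi_j)`.
#' The numerator `u` is a dimensionless sine of an angular offset, so the
#' printed width `sigma_g` (degrees) is converted to radians before dividing;
#' this yields an effective ring width of about `sigma_g` degrees.
#'
#' @param theta_j,phi_j unit elevation and azimuth in the sensor frame
#'   (degrees, vectorised).
#' @param theta_t,phi_t tilt of the sensor zenith (degrees; `theta_t = 90`
#'   means no tilt).
#' @param theta_g,sigma_g ring radius and width in degrees.
#' @return gating weights in `(0, 1]`.
#' @examples
#' gating_weight(50, 0, 90, 0)   # on the ring: 1
#' gating_weight(90, 0, 90, 0)   # zenith unit: ~0.018
#' @export
gating_weight <- function(theta_j, phi_j, theta_t = 90, phi_t = 0,
                          theta_g = 40, sigma_g = 13) {
  u <- cosd(theta_g + theta_j) * sind(theta_t) -
    sind(theta_g + theta_j) * cosd(theta_t) * cosd(phi_t - phi_j)
  exp(-0.5 * (u / (sigma_g * .D2R))^2)
}

# Gating weights for a posed array. The gating ring lives in sensor
# coordinates: (theta_t, phi_t) passed to gating_weight() is the position of
# the sky zenith on the sensor, which for a zero-roll tilt towards world
# azimuth phi_t is (theta_t, phi_t + 180 - yaw). With that reading the u = 0
# locus of the Gaussian ring coincides with the circle of world zenith
# distance theta_g, i.e. the gate focuses the units that currently view the
# most informative sky ring.
array_gate <- function(compass, array) {
  if (!compass$gating) return(rep(1, array$n))
  gating_weight(array$units$theta, array$units$phi,
                array$pose$theta_t,
                array$pose$phi_t + 180 - array$pose$yaw,
                compass$theta_g, compass$sigma_g)
}

#' Solar-layer response
#'
#' Sum-of-sinusoids projection of the POL population onto `n_sol` neurons:
#' `r_sol[xi] = sum_j (n_sol / n_pol) sin(alpha_j - pref_xi) g_j r_pol[j]`.
#' With gating disabled all `g_j = 1`.
#'
#' @param pol a [sense()] result (or any list with `r_pol`).
#' @param array the posed `sensor_array` that produced `pol`.
#' @param compass a [build_compass()] model.
#' @param gate optional precomputed gating weights (length n).
#' @return numeric vector of length `n_sol`.
#' @export
sol_response <- function(pol, array, compass, gate = NULL) {
  stopifnot(length(pol$r_pol) == array$n)
  if (is.null(gate)) gate <- array_gate(compass, array)
  W <- sind(outer(compass$sol_prefs, array$units$alpha,
                  function(p, a) a - p))            # n_sol x n
  drop(W %*% (gate * pol$r_pol)) * compass$n_sol / array$n
}

#' Decode a population response
#'
#' Fundamental discrete-Fourier component of an `m`-neuron population:
#' `R = sum_xi r[xi] exp(-i 360 (xi - 1) / m)`; the decoded angle is the
#' argument of the conjugate of `R` (raw, before any calibration offset) and
#' the confidence is `tau = |R|`. The DC component is ignored, so adding a
#' constant to all responses changes nothing.
#'
#' @param r numeric response vector (length >= 4), or a matrix with one
#'   population per column.
#' @return a list with `angle` (degrees in `[0, 360)`), `tau` (`>= 0`) and
#'   `ok` (`FALSE` where the fundamental vanishes and the angle is
#'   undefined).
#' @export
decode_population <- function(r) {
  if (is.null(dim(r))) r <- matrix(r, ncol = 1L)
  m <- nrow(r)
  stopifnot(m >= 4)
  z <- exp(-1i * 2 * pi * (seq_len(m) - 1) / m)
  R <- drop(z %*% r)
  tau <- Mod(R)
  ok <- tau > 1e-9
  angle <- ifelse(ok, wrap360(Arg(Conj(R)) / .D2R), NA_real_)
  list(angle = angle, tau = tau, ok = ok)
}

#' Uncertainty of the azimuth estimate
#'
#' `sigma_s = 4 / tau^2` degrees: monotone decreasing in the confidence.
#' `tau = 0` maps to `Inf`.
#'
#' @param tau confidence (vectorised, `>= 0`).
#' @return uncertainty in degrees.
#' @export
uncertainty <- function(tau) {
  stopifnot(all(tau >= 0))
  ifelse(tau == 0, Inf, 4 / tau^2)
}

#' Solar elevation inferred from confidence
#'
#' Heuristic inverse relation between compass confidence and solar
#' elevation: `theta = 75 + 26 * (asin(2.855 - 3.5 tau) / 90 - 1)` degrees,
#' with `tau` clamped to `[0.53, 1.1]` (out-of-range confidences give the
#' corresponding boundary elevation).
#'
#' @param tau confidence (vectorised, `>= 0`).
#' @return elevation estimate in degrees.
#' @examples
#' estimate_elevation(0.53)    # 75
#' estimate_elevation(0.8157)  # ~49
#' @export
estimate_elevation <- function(tau) {
  stopifnot(all(tau >= 0))
  tau <- pmin(1.1, pmax(0.53, tau))
  75 + 26 * (asind(2.855 - 3.5 * tau) / 90 - 1)
}

#' Rate of change of the solar azimuth
#'
#' Ephemeris approximation `d phi_s / dt = exp((theta - 36) / 10) + 9`
#' degrees per hour, monotone increasing in the (estimated) solar elevation
#' and never below 9 deg/h.
#'
#' @param theta solar elevation in degrees (vectorised).
#' @return azimuth change rate in degrees per hour.
#' @examples
#' azimuth_rate(36)  # 10
#' @export
azimuth_rate <- function(theta) exp((theta - 36) / 10) + 9

#' True-compass-layer response
#'
#' Cosine projection of the solar layer onto the TCL population:
#' `r_tcl[k] = sum_xi (n_tcl / n_sol) cos(pref_k - pref_xi) r_sol[xi]`.
#' With the TCL preferred angles at their initial values this is an identity
#' rotation (the decoded angles of SOL and TCL agree); shifting all
#' preferred angles by `D` shifts the decoded TCL angle by `-D`, which is
#' how the time compensation keeps the decoded heading geocentric while the
#' sun moves.
#'
#' @param r_sol solar-layer response vector.
#' @param compass a [build_compass()] model.
#' @param tcl_prefs optional preferred angles (degrees) overriding
#'   `compass$tcl_prefs`.
#' @return numeric vector of length `n_tcl`.
#' @export
tcl_response <- function(r_sol, compass, tcl_prefs = NULL) {
  if (is.null(tcl_prefs)) tcl_prefs <- compass$tcl_prefs
  W <- cosd(outer(tcl_prefs, compass$sol_prefs, `-`))  # n_tcl x n_sol
  drop(W %*% r_sol) * compass$n_tcl / compass$n_sol
}

#' Advance the TCL preferred angles with passing time
#'
#' Applies the ephemeris update: every preferred angle advances by
#' `azimuth_rate(estimate_elevation(tau)) * dt` degrees in the clockwise
#' sense (the sun always moves clockwise, in the northern hemisphere, in
#' this convention). The update is skipped when the confidence is below the
#' elevation-inversion domain floor (`tau < 0.53`).
#'
#' @param tcl_prefs current preferred angles in degrees.
#' @param tau current confidence of the azimuth estimate.
#' @param dt elapsed time in hours (`>= 0`).
#' @return updated preferred angles, wrapped to `[0, 360)`.
#' @export
update_tcl_prefs <- function(tcl_prefs, tau, dt) {
  stopifnot(dt >= 0, tau >= 0)
  if (dt == 0 || tau < 0.53) return(wrap360(tcl_prefs))
  wrap360(tcl_prefs + azimuth_rate(estimate_elevation(tau)) * dt)
}

#' Calibrate the decoder offset of a compass for an array
#'
#' The index phase of the population decoder and the preferred-angle
#' convention of the solar layer differ by a fixed rotation; this constant
#' is fixed once by requiring that the decoded azimuth equals the true solar
#' azimuth on clear-sky, untilted reference scenes (sun at 30 deg elevation,
#' eight azimuths; the circular mean of the residuals is absorbed into the
#' offset).
#'
#' @param compass a [build_compass()] model.
#' @param array a [build_dra()] array (pose is ignored; calibration is
#'   untilted).
#' @param d_max maximum degree of polarisation of the reference sky.
#' @return the compass with `offset` set (degrees).
#' @export
calibrate_compass <- function(compass, array, d_max = 0.75) {
  arr <- pose_sensor(array, 90, 0, 0)
  az <- seq(0, 315, by = 45)
  sv <- sph_to_vec(rep(30, length(az)), az)
  rp <- pol_response_matrix(arr, sv, d_max)
  gate <- array_gate(compass, arr)
  W <- sind(outer(compass$sol_prefs, arr$units$alpha,
                  function(p, a) a - p))
  rs <- (W %*% (gate * rp)) * compass$n_sol / arr$n
  dec <- decode_population(rs)
  res <- wrap180(az - dec$angle)
  compass$offset <- wrap360(atan2d(mean(sind(res)), mean(cosd(res))))
  compass
}

#' Single-scene compass estimate
#'
#' Runs the full chain for one sky scene: sense, gate, solar layer, decode
#' (with calibration offset), uncertainty and elevation estimate, plus the
#' TCL response under the current preferred angles.
#'
#' @param compass a [build_compass()] model (calibrated; if not, it is
#'   calibrated on the fly for `array`).
#' @param array a posed `sensor_array`.
#' @param sky a [sky_state()].
#' @param eta disturbance fraction in `[0, 1]`.
#' @param seed seed for the disturbance mask.
#' @return an object of class `compass_estimate`: list with `azimuth`
#'   (degrees, sensor frame, calibrated), `tau`, `sigma`, `elevation`
#'   (estimated solar elevation), `r_pol`, `r_sol`, `r_tcl`, `tcl_azimuth`
#'   (decoded TCL angle plus offset) and `ok`.
#' @export
compass_estimate <- function(compass, array, sky, eta = 0, seed = NULL) {
  if (is.null(compass$offset)) compass <- calibrate_compass(compass, array,
                                                            sky$cfg$d_max)
  pol <- sense(sky, array, eta, seed)
  gate <- array_gate(compass, array)
  rs <- sol_response(pol, array, compass, gate)
  dec <- decode_population(rs)
  rt <- tcl_response(rs, compass)
  dect <- decode_population(rt)
  structure(list(
    azimuth = wrap360(dec$angle + compass$offset),
    tau = dec$tau, sigma = uncertainty(dec$tau),
    elevation = estimate_elevation(dec$tau),
    r_pol = pol$r_pol, failed = pol$failed, gate = gate,
    r_sol = rs, r_tcl = rt,
    tcl_azimuth = wrap360(dect$angle + compass$offset),
    tcl_tau = dect$tau, ok = dec$ok),
    class = "compass_estimate")
}

#' @export
print.compass_estimate <- function(x, ...) {
  cat(sprintf("<compass_estimate> azimuth %.2f deg, tau %.3f (sigma %.2f deg), elevation est %.1f deg\n",
              x$azimuth, x$tau, x$sigma, x$elevation))
  invisible(x)
}

# Vectorised prediction over many suns for a fixed pose: returns a data
# frame with true and estimated azimuths, confidence, and the tilt. Fresh
# independent failure masks are drawn per sun when eta > 0.
compass_predict <- function(compass, array, suns, eta = 0, seed = NULL,
                            d_max = 0.75) {
  if (is.null(compass$offset)) compass <- calibrate_compass(compass, array,
                                                            d_max)
  sv <- sph_to_vec(suns$elevation, suns$azimuth)
  rp <- pol_response_matrix(array, sv, d_max)
  if (eta > 0) {
    k <- round(eta * array$n)
    if (k > 0) {
      masks <- with_seed(seed, replicate(nrow(sv), sample.int(array$n, k)))
      masks <- matrix(masks, nrow = k)
      for (s in seq_len(nrow(sv))) rp[masks[, s], s] <- 0
    }
  }
  gate <- array_gate(compass, array)
  W <- sind(outer(compass$sol_prefs, array$units$alpha,
                  function(p, a) a - p))
  rs <- (W %*% (gate * rp)) * compass$n_sol / array$n
  dec <- decode_population(rs)
  data.frame(elevation_true = suns$elevation,
             azimuth_true = suns$azimuth,
             azimuth_est = wrap360(dec$angle + compass$offset),
             tau = dec$tau,
             delta = 90 - array$pose$theta_t)
}
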