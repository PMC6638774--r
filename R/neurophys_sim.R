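# Simulated electrophysiology: tuning curves of the TCL compass neurons
# under the classic bench stimulus (uniform light through a rotating linear
# polariser) versus a rotating natural sky, with circular-statistics
# extraction of preferred directions. The headline property: the same model
# is 180-degree periodic under the polariser (axial e-vector cue only) but
# 360-degree periodic under the sky, where the polarisation gradient breaks
# the axial symmetry.

# TCL responses for a POL response matrix (n x m) at zero tilt
.tcl_from_pol <- function(compass, array, rp) {
  gate <- array_gate(compass, array)
  W <- sind(outer(compass$sol_prefs, array$units$alpha,
                  function(p, a) a - p))
  rs <- (W %*% (gate * rp)) * compass$n_sol / array$n
  Wt <- cosd(outer(compass$tcl_prefs, compass$sol_prefs, `-`))
  (Wt %*% rs) * compass$n_tcl / compass$n_sol
}

#' Rotating-polariser experiment
#'
#' Exposes the untilted sensor array to a uniform light source seen through
#' a rotating linear polariser: every unit receives the same luminance,
#' full polarisation (`d = 1`, maximising contrast as on a bench) and a
#' common e-vector angle, swept over a full rotation. Per trial, a fraction
#' `eta` of units fails (fixed mask within a trial, redrawn across trials).
#'
#' @param compass a [build_compass()] model.
#' @param array a [build_dra()] array.
#' @param angle_step polariser angle step in degrees.
#' @param n_trials number of trials.
#' @param eta disturbance fraction.
#' @param seed master seed.
#' @return an object of class `tuning_set`: list with `angles`, `response`
#'   (array trials x angles x neurons), `condition = "polariser"`.
#' @export
rotating_polariser_experiment <- function(compass, array, angle_step = 10,
                                          n_trials = 10, eta = 0,
                                          seed = 1) {
  angles <- seq(0, 360 - angle_step, by = angle_step)
  # all units see aop = beta in the common (zenith-projected) frame; the
  # response depends on beta - alpha_j through the Malus opponent chain
  m <- cosd(2 * outer(array$units$alpha, angles, function(a, b) b - a))
  rp_all <- (sqrt((1 + m) / 2) - sqrt((1 - m) / 2)) /
    (sqrt((1 + m) / 2) + sqrt((1 - m) / 2))
  resp <- array(0, dim = c(n_trials, length(angles), compass$n_tcl))
  for (tr in seq_len(n_trials)) {
    rp <- rp_all
    rp[failure_mask(array$n, eta,
                    derive_seed(seed, "polariser-mask", tr)), ] <- 0
    resp[tr, , ] <- t(.tcl_from_pol(compass, array, rp))
  }
  structure(list(angles = angles, response = resp,
                 condition = "polariser", eta = eta),
            class = "tuning_set")
}

#' Rotating-sky experiment
#'
#' Rotates a natural sky (sun at fixed elevation) a full 360 degrees around
#' the untilted sensor and records the TCL responses.
#'
#' @param compass,array model and sensor.
#' @param sun_elevation solar elevation in degrees (default 30).
#' @param angle_step sky rotation step in degrees.
#' @param n_trials number of trials (default 100).
#' @param eta disturbance fraction (default 0.5).
#' @param seed master seed.
#' @param d_max maximum sky degree of polarisation.
#' @return a `tuning_set` with `condition = "sky"`.
#' @export
rotating_sky_experiment <- function(compass, array, sun_elevation = 30,
                                    angle_step = 10, n_trials = 100,
                                    eta = 0.5, seed = 1, d_max = 0.75) {
  angles <- seq(0, 360 - angle_step, by = angle_step)
  posed <- pose_sensor(array, 90, 0)
  sv <- sph_to_vec(rep(sun_elevation, length(angles)), angles)
  rp_all <- pol_response_matrix(posed, sv, d_max)
  resp <- array(0, dim = c(n_trials, length(angles), compass$n_tcl))
  for (tr in seq_len(n_trials)) {
    rp <- rp_all
    rp[failure_mask(array$n, eta,
                    derive_seed(seed, "sky-mask", tr)), ] <- 0
    resp[tr, , ] <- t(.tcl_from_pol(compass, array, rp))
  }
  structure(list(angles = angles, response = resp, condition = "sky",
                 eta = eta),
            class = "tuning_set")
}

#' Preferred direction of a tuning curve
#'
#' Response-weighted circular mean of the stimulus angles (angles doubled
#' first when the stimulus is axial, the mean halved), with a Rayleigh test
#' of the weighted resultant; the preferred direction is undefined when the
#' test is not significant.
#'
#' @param angles stimulus angles in degrees, covering the full rotation.
#' @param response response at each angle (one neuron).
#' @param axial logical; `TRUE` for axial stimuli (polariser), `FALSE` for
#'   circular (sky rotation).
#' @param alpha significance level of the Rayleigh test.
#' @return list with `phi_max` (degrees; `NA` when not significant),
#'   `resultant` (weighted mean resultant length), `p_value`.
#' @export
preferred_direction <- function(angles, response, axial = FALSE,
                                alpha = 0.05) {
  stopifnot(length(angles) == length(response))
  w <- response - min(response)
  if (sum(w) <= 0) return(list(phi_max = NA_real_, resultant = 0,
                               p_value = 1))
  mfac <- if (axial) 2 else 1
  z <- sum(w * exp(1i * mfac * angles * .D2R)) / sum(w)
  rbar <- Mod(z)
  n <- length(angles)
  # Rayleigh test on the weighted resultant (Z = n * rbar^2)
  Z <- n * rbar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(1, max(0, p))
  phi <- if (p < alpha) wrap360(Arg(z) / .D2R) / mfac else NA_real_
  list(phi_max = phi, resultant = rbar, p_value = p)
}

#' Dominant period of a tuning curve
#'
#' Compares the discrete Fourier power at one and two cycles per full
#' rotation and returns the dominant period (360 or 180 degrees).
#'
#' @param response response over a full rotation of equally spaced angles.
#' @return list with `period` (360 or 180) and the two `power` values.
#' @export
dominant_period <- function(response) {
  f <- stats::fft(response - mean(response))
  p1 <- Mod(f[2])^2
  p2 <- Mod(f[3])^2
  list(period = if (p1 >= p2) 360 else 180, power = c(p1 = p1, p2 = p2))
}

#' Preferred directions of all neurons in a tuning set
#'
#' Per-trial preferred directions via [preferred_direction()], combined
#' across trials by a circular mean (in the doubled domain when axial), and
#' a linear fit of preferred direction against neuron index whose slope
#' estimates the per-column tuning spacing.
#'
#' @param ts a `tuning_set`.
#' @param axial logical; defaults to `TRUE` for the polariser condition.
#' @return list with `by_trial` (matrix trials x neurons of phi_max),
#'   `mean_phi_max` (per neuron), and `slope` (degrees per column, from a
#'   grid search over circular-linear fits).
#' @export
tuning_summary <- function(ts, axial = ts$condition == "polariser") {
  nt <- dim(ts$response)[1]; nn <- dim(ts$response)[3]
  by_trial <- matrix(NA_real_, nt, nn)
  for (tr in seq_len(nt)) for (k in seq_len(nn)) {
    by_trial[tr, k] <- preferred_direction(ts$angles, ts$response[tr, , k],
                                           axial = axial)$phi_max
  }
  mfac <- if (axial) 2 else 1
  mean_phi <- apply(by_trial, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    wrap360(Arg(mean(exp(1i * mfac * v * .D2R))) / .D2R) / mfac
  })
  # circular-linear fit: phi_max ~ slope * index, slope over a fine grid
  span <- 360 / mfac
  idx <- seq_len(nn) - 1
  ok <- !is.na(by_trial)
  ii <- matrix(rep(idx, each = nt), nt, nn)[ok]
  vv <- by_trial[ok]
  slopes <- seq(-span / 2, span / 2, by = 0.25)
  cost <- vapply(slopes, function(s) {
    r <- (vv - s * ii) * mfac * .D2R
    -Mod(mean(exp(1i * r)))
  }, numeric(1))
  list(by_trial = by_trial, mean_phi_max = mean_phi,
       slope = slopes[which.min(cost)])
}

#' Export a tuning set as a tidy table
#'
#' @param ts a `tuning_set`.
#' @param file optional CSV path.
#' @return data frame with columns `neuron`, `condition`, `angle`,
#'   `response` (trial mean).
#' @export
tuning_table <- function(ts, file = NULL) {
  mean_resp <- apply(ts$response, c(2, 3), mean)
  out <- data.frame(
    neuron = rep(seq_len(ncol(mean_resp)), each = nrow(mean_resp)),
    condition = ts$condition,
    angle = rep(ts$angles, ncol(mean_resp)),
    response = as.vector(mean_resp))
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
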