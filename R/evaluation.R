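# Quantitative evaluation: the objective J (mean absolute wrapped azimuth
# error) over ensembles of tilts and sun positions, disturbance curves, and
# parameter sweeps over the gating ring, the sensor layout and the compass
# population sizes.

#' Wrapped absolute angular error
#'
#' `|((phi - phi_est + 180) mod 360) - 180|` in degrees, in `[0, 180]`.
#'
#' @param phi,phi_est true and estimated angles in degrees (vectorised).
#' @return absolute angular error in degrees.
#' @examples
#' angular_error(10, 350)  # 20
#' @export
angular_error <- function(phi, phi_est) {
  abs(((phi - phi_est + 180) %% 360) - 180)
}

#' Evaluation protocol
#'
#' The default protocol matches the tilt ensemble used throughout the
#' package's evaluation: one untilted pose plus 8 poses on a 30 degree tilt
#' ring and 8 on a 60 degree ring (tilt azimuths at 45 degree spacing), with
#' 500 quasi-uniform sun positions per pose — 8500 predictions in total.
#'
#' @param n_sun sun positions per tilt pose.
#' @param deltas tilt magnitudes (degrees) of the tilt rings.
#' @param ring_counts number of tilt azimuths per ring.
#' @param include_zenith logical; include the untilted pose.
#' @param eta disturbance fraction applied to every prediction.
#' @param seed master seed; sun ensembles and disturbance masks are drawn
#'   from named sub-streams per tilt pose.
#' @return an object of class `eval_protocol` with a `tilts` data frame
#'   (`delta`, `theta_t`, `phi_t`).
#' @export
eval_protocol <- function(n_sun = 500, deltas = c(30, 60),
                          ring_counts = c(8, 8), include_zenith = TRUE,
                          eta = 0, seed = 1) {
  stopifnot(length(deltas) == length(ring_counts), eta >= 0, eta <= 1)
  tilts <- if (include_zenith) data.frame(delta = 0, theta_t = 90, phi_t = 0)
           else data.frame(delta = numeric(), theta_t = numeric(),
                           phi_t = numeric())
  for (i in seq_along(deltas)) {
    ph <- (seq_len(ring_counts[i]) - 1) * 360 / ring_counts[i]
    tilts <- rbind(tilts, data.frame(delta = deltas[i],
                                     theta_t = 90 - deltas[i], phi_t = ph))
  }
  structure(list(n_sun = n_sun, tilts = tilts, eta = eta, seed = seed),
            class = "eval_protocol")
}

#' @export
print.eval_protocol <- function(x, ...) {
  cat(sprintf("<eval_protocol> %d tilt poses x %d suns = %d predictions, eta = %g, seed = %s\n",
              nrow(x$tilts), x$n_sun, nrow(x$tilts) * x$n_sun, x$eta,
              format(x$seed)))
  invisible(x)
}

#' Run the evaluation objective
#'
#' For every tilt pose of the protocol, draws a fresh quasi-uniform sun
#' ensemble, runs the full sensing and decoding chain, and aggregates the
#' wrapped absolute azimuth error into the objective
#' `J = mean(angular_error)` with its standard error, plus the mean
#' confidence.
#'
#' @param compass a [build_compass()] model.
#' @param array a [build_dra()] sensor array.
#' @param protocol an [eval_protocol()].
#' @param d_max maximum sky degree of polarisation.
#' @param keep_records logical; retain the per-prediction record table.
#' @return an object of class `eval_result`: list with `J`, `se`,
#'   `tau_mean`, `n`, a per-tilt-level summary `by_delta` (columns `delta`,
#'   `J`, `se`, `tau_mean`, `n`) and (optionally) `records`.
#' @export
run_objective <- function(compass, array, protocol = eval_protocol(),
                          d_max = 0.75, keep_records = TRUE) {
  if (is.null(compass$offset)) compass <- calibrate_compass(compass, array,
                                                            d_max)
  recs <- vector("list", nrow(protocol$tilts))
  for (t in seq_len(nrow(protocol$tilts))) {
    tl <- protocol$tilts[t, ]
    suns <- sample_hemisphere(protocol$n_sun,
                              seed = derive_seed(protocol$seed, "sun", t))
    posed <- pose_sensor(array, tl$theta_t, tl$phi_t)
    p <- compass_predict(compass, posed, suns, eta = protocol$eta,
                         seed = derive_seed(protocol$seed, "mask", t),
                         d_max = d_max)
    p$tilt <- t
    p$phi_t <- tl$phi_t
    recs[[t]] <- p
  }
  records <- do.call(rbind, recs)
  records$error <- angular_error(records$azimuth_true, records$azimuth_est)
  agg <- function(r) c(J = mean(r$error),
                       se = stats::sd(r$error) / sqrt(nrow(r)),
                       tau_mean = mean(r$tau), n = nrow(r))
  by_delta <- do.call(rbind, lapply(split(records, records$delta),
                                    function(r) as.data.frame(t(agg(r)))))
  by_delta <- cbind(delta = as.numeric(rownames(by_delta)), by_delta)
  rownames(by_delta) <- NULL
  tot <- agg(records)
  structure(list(J = unname(tot["J"]), se = unname(tot["se"]),
                 tau_mean = unname(tot["tau_mean"]), n = unname(tot["n"]),
                 by_delta = by_delta,
                 records = if (keep_records) records else NULL,
                 eta = protocol$eta),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> J = %.2f deg +/- %.2f (SE), mean tau = %.3f, N = %d, eta = %g\n",
              x$J, x$se, x$tau_mean, x$n, x$eta))
  print(x$by_delta, digits = 4)
  invisible(x)
}

#' Error and confidence against disturbance level
#'
#' Runs the untilted compass over a grid of disturbance levels, averaging
#' over several independent mask seeds per level.
#'
#' @param compass,array model and sensor.
#' @param etas disturbance grid in `[0, 1]`.
#' @param n_sun sun positions per seed.
#' @param n_seeds independent repetitions per level.
#' @param seed master seed.
#' @param d_max maximum sky degree of polarisation.
#' @return data frame with one row per level: `eta`, `J`, `se`, `tau_mean`,
#'   `sigma_median` (median uncertainty, degrees; the median is
#'   used because near-degenerate scenes with vanishing confidence make
#'   the mean uncertainty diverge).
#' @export
disturbance_curve <- function(compass, array, etas = c(0, 0.2, 0.4, 0.6,
                                                       0.8, 0.97),
                              n_sun = 200, n_seeds = 20, seed = 1,
                              d_max = 0.75) {
  if (is.null(compass$offset)) compass <- calibrate_compass(compass, array,
                                                            d_max)
  posed <- pose_sensor(array, 90, 0)
  out <- lapply(seq_along(etas), function(i) {
    errs <- taus <- c()
    for (s in seq_len(n_seeds)) {
      suns <- sample_hemisphere(n_sun,
                                seed = derive_seed(seed, "dist-sun", s))
      p <- compass_predict(compass, posed, suns, eta = etas[i],
                           seed = derive_seed(seed, "dist-mask",
                                              i * 1000 + s),
                           d_max = d_max)
      errs <- c(errs, angular_error(p$azimuth_true, p$azimuth_est))
      taus <- c(taus, p$tau)
    }
    data.frame(eta = etas[i], J = mean(errs),
               se = stats::sd(errs) / sqrt(length(errs)),
               tau_mean = mean(taus),
               sigma_median = stats::median(uncertainty(taus)))
  })
  do.call(rbind, out)
}

#' Grid search over the gating-ring parameters
#'
#' Computes the objective for every combination of ring radius and width on
#' the tilt protocol. POL responses are independent of the gating, so they
#' are computed once per tilt pose and reused across the grid.
#'
#' @param array sensor array.
#' @param theta_g_grid,sigma_g_grid parameter grids in degrees.
#' @param protocol an [eval_protocol()].
#' @param n_sol solar-layer size.
#' @param d_max maximum sky degree of polarisation.
#' @return list with `grid` (data frame `theta_g`, `sigma_g`, `J`, `se`) and
#'   `argmin` (row of the grid with the lowest `J`).
#' @export
sweep_gating <- function(array, theta_g_grid = seq(20, 60, by = 5),
                         sigma_g_grid = seq(5, 30, by = 4),
                         protocol = eval_protocol(n_sun = 100),
                         n_sol = 8, d_max = 0.75) {
  base <- calibrate_compass(build_compass(n_sol = n_sol), array, d_max)
  W <- sind(outer(base$sol_prefs, array$units$alpha,
                  function(p, a) a - p))
  cells <- expand.grid(theta_g = theta_g_grid, sigma_g = sigma_g_grid)
  errs <- matrix(0, nrow(cells), 0)
  err_sum <- rep(0, nrow(cells)); err_sq <- rep(0, nrow(cells)); nn <- 0
  for (t in seq_len(nrow(protocol$tilts))) {
    tl <- protocol$tilts[t, ]
    suns <- sample_hemisphere(protocol$n_sun,
                              seed = derive_seed(protocol$seed, "sun", t))
    posed <- pose_sensor(array, tl$theta_t, tl$phi_t)
    sv <- sph_to_vec(suns$elevation, suns$azimuth)
    rp <- pol_response_matrix(posed, sv, d_max)
    for (c_i in seq_len(nrow(cells))) {
      g <- gating_weight(array$units$theta, array$units$phi,
                         tl$theta_t, tl$phi_t + 180,
                         cells$theta_g[c_i], cells$sigma_g[c_i])
      dec <- decode_population((W %*% (g * rp)) * n_sol / array$n)
      e <- angular_error(suns$azimuth, wrap360(dec$angle + base$offset))
      err_sum[c_i] <- err_sum[c_i] + sum(e)
      err_sq[c_i] <- err_sq[c_i] + sum(e^2)
    }
    nn <- nn + protocol$n_sun
  }
  cells$J <- err_sum / nn
  cells$se <- sqrt(pmax(0, err_sq / nn - cells$J^2) / nn)
  list(grid = cells, argmin = cells[which.min(cells$J), ])
}

#' Grid search over the sensor layout
#'
#' Objective per (number of units, receptive field) combination on the tilt
#' protocol.
#'
#' @param n_grid,omega_grid layout grids.
#' @param protocol an [eval_protocol()].
#' @param gating logical; evaluate with the tilt gate enabled.
#' @param d_max maximum sky degree of polarisation.
#' @return data frame with columns `n`, `omega`, `J`, `se`, `tau_mean`.
#' @export
sweep_layout <- function(n_grid = c(12, 24, 36, 48, 60, 90, 120),
                         omega_grid = 56,
                         protocol = eval_protocol(n_sun = 100),
                         gating = TRUE, d_max = 0.75) {
  cells <- expand.grid(n = n_grid, omega = omega_grid)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    arr <- build_dra(n = cells$n[i], omega = cells$omega[i])
    cmp <- calibrate_compass(build_compass(gating = gating), arr, d_max)
    r <- run_objective(cmp, arr, protocol, d_max, keep_records = FALSE)
    data.frame(n = cells$n[i], omega = cells$omega[i], J = r$J, se = r$se,
               tau_mean = r$tau_mean)
  })
  do.call(rbind, out)
}

#' Grid search over the compass population sizes
#'
#' Objective per (n_SOL, n_TCL) combination; the azimuth is decoded from the
#' TCL layer so that both population sizes matter.
#'
#' @param nsol_grid,ntcl_grid population grids (values >= 4).
#' @param array sensor array.
#' @param protocol an [eval_protocol()].
#' @param d_max maximum sky degree of polarisation.
#' @return data frame with columns `n_sol`, `n_tcl`, `J`, `se`.
#' @export
sweep_populations <- function(nsol_grid = c(4, 8, 16), ntcl_grid = 8,
                              array = build_dra(),
                              protocol = eval_protocol(n_sun = 100),
                              d_max = 0.75) {
  cells <- expand.grid(n_sol = nsol_grid, n_tcl = ntcl_grid)
  tcl_chain <- function(cmp, posed, sv) {
    rp <- pol_response_matrix(posed, sv, d_max)
    gate <- array_gate(cmp, posed)
    W <- sind(outer(cmp$sol_prefs, posed$units$alpha,
                    function(p, a) a - p))
    rs <- (W %*% (gate * rp)) * cmp$n_sol / posed$n
    Wt <- cosd(outer(cmp$tcl_prefs, cmp$sol_prefs, `-`))
    decode_population((Wt %*% rs) * cmp$n_tcl / cmp$n_sol)
  }
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cmp <- build_compass(n_sol = cells$n_sol[i], n_tcl = cells$n_tcl[i])
    # calibrate the decoder offset through the TCL chain itself (the index
    # phase of the decoder depends on the population size)
    az <- seq(0, 315, by = 45)
    dec0 <- tcl_chain(cmp, pose_sensor(array, 90, 0),
                      sph_to_vec(rep(30, 8), az))
    res <- wrap180(az - dec0$angle)
    offset <- wrap360(atan2d(mean(sind(res)), mean(cosd(res))))
    errs <- c()
    for (t in seq_len(nrow(protocol$tilts))) {
      tl <- protocol$tilts[t, ]
      suns <- sample_hemisphere(protocol$n_sun,
                                seed = derive_seed(protocol$seed, "sun", t))
      posed <- pose_sensor(array, tl$theta_t, tl$phi_t)
      dec <- tcl_chain(cmp, posed, sph_to_vec(suns$elevation, suns$azimuth))
      errs <- c(errs, angular_error(suns$azimuth,
                                    wrap360(dec$angle + offset)))
    }
    data.frame(n_sol = cells$n_sol[i], n_tcl = cells$n_tcl[i],
               J = mean(errs), se = stats::sd(errs) / sqrt(length(errs)))
  })
  do.call(rbind, out)
}
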