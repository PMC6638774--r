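test_that("gating weights reproduce the ring geometry", {
  # untilted: a unit on the ring (elevation 90 - theta_g) gets weight 1
  expect_equal(gating_weight(50, 0, 90, 0), 1)
  # untilted zenith unit: u = cos(130 deg), sigma in radians
  expect_equal(gating_weight(90, 123, 90, 0), 0.018, tolerance = 1e-2)
  # gating disabled: all weights 1
  cmp <- build_compass(gating = FALSE)
  arr <- pose_sensor(build_dra(), 60, 45)
  expect_true(all(polcompass:::array_gate(cmp, arr) == 1))
  # weights always in (0, 1]
  g <- gating_weight(seq(0, 90, 5), seq(0, 350, length.out = 19), 60, 120)
  expect_true(all(g > 0 & g <= 1))
})

test_that("the solar layer decodes the azimuth on a clear untilted sky", {
  arr <- build_dra()
  cmp <- calibrate_compass(build_compass(), arr)
  for (az in c(0, 77, 180, 293)) {
    est <- compass_estimate(cmp, arr, sky_state(sun_position(30, az)))
    expect_lt(angular_error(az, est$azimuth), 1)
  }
  # zero input gives zero output
  pol0 <- list(r_pol = rep(0, 60))
  expect_equal(sol_response(pol0, arr, cmp), rep(0, 8))
})

test_that("duplicating every unit leaves the solar response unchanged", {
  arr <- build_dra()
  cmp <- build_compass()
  sky <- sky_state(sun_position(30, 120))
  pol <- sense(sky, arr)
  rs1 <- sol_response(pol, arr, cmp)
  arr2 <- arr
  arr2$n <- 120L
  arr2$units <- rbind(arr$units, arr$units)
  pol2 <- list(r_pol = rep(pol$r_pol, 2))
  rs2 <- sol_response(pol2, arr2, cmp,
                      gate = rep(polcompass:::array_gate(cmp, arr), 2))
  expect_equal(rs1, rs2, tolerance = 1e-12)
})

test_that("the population decoder recovers phase and amplitude", {
  # uniform response: fundamental vanishes
  d0 <- decode_population(rep(0.3, 8))
  expect_false(d0$ok)
  expect_equal(d0$tau, 0, tolerance = 1e-12)
  # pure sinusoid over 8 neurons at 45 deg spacing: tau = 4 and the phase
  # is recovered after the fixed index-phase offset of +45 deg
  for (phi0 in c(0, 33, 190, 310)) {
    r <- cos(((1:8) * 45 - phi0) * pi / 180)
    d <- decode_population(r)
    expect_equal(d$tau, 4, tolerance = 1e-9)
    expect_lt(abs(circ_diff(d$angle + 45, phi0)), 1e-9)
    # adding a DC offset changes nothing
    d2 <- decode_population(r + 5)
    expect_equal(d2$angle, d$angle, tolerance = 1e-9)
    expect_equal(d2$tau, d$tau, tolerance = 1e-9)
  }
})

test_that("uncertainty and elevation transforms match their closed forms", {
  expect_equal(uncertainty(1), 4)
  expect_equal(uncertainty(2), 1)
  expect_equal(uncertainty(0), Inf)
  taus <- seq(0.1, 3, by = 0.1)
  expect_true(all(diff(uncertainty(taus)) < 0))

  expect_equal(estimate_elevation(0.53), 75, tolerance = 1e-9)
  expect_equal(estimate_elevation(2.855 / 3.5), 49, tolerance = 1e-9)
  expect_equal(estimate_elevation(1.2), estimate_elevation(1.1))
  expect_equal(estimate_elevation(0.1), estimate_elevation(0.53))

  expect_equal(azimuth_rate(36), 10)
  expect_equal(azimuth_rate(59), exp(2.3) + 9, tolerance = 1e-9)
  expect_true(all(diff(azimuth_rate(seq(0, 90, 5))) > 0))
  expect_true(all(azimuth_rate(seq(-20, 90, 5)) >= 9))
})

test_that("the TCL layer is an identity rotation initially and rotates with its preferred angles", {
  arr <- build_dra()
  cmp <- calibrate_compass(build_compass(), arr)
  pol <- sense(sky_state(sun_position(30, 210)), arr)
  rs <- sol_response(pol, arr, cmp)
  rt <- tcl_response(rs, cmp)
  ds <- decode_population(rs)
  dt <- decode_population(rt)
  expect_lt(abs(circ_diff(ds$angle, dt$angle)), 1e-9)
  # shifting all preferred angles by D shifts the decoded angle by -D
  for (D in c(10, 120, 250)) {
    rtD <- tcl_response(rs, cmp, tcl_prefs = cmp$tcl_prefs + D)
    dtD <- decode_population(rtD)
    expect_lt(abs(circ_diff(dtD$angle, dt$angle - D)), 1e-6)
  }
  expect_equal(tcl_response(rep(0, 8), cmp), rep(0, 8))
})

test_that("the ephemeris update advances preferred angles clockwise when confident", {
  prefs <- (1:8) * 45
  expect_equal(update_tcl_prefs(prefs, 0.8, 0), prefs %% 360)
  # below the confidence floor the update is skipped
  expect_equal(update_tcl_prefs(prefs, 0.4, 2), prefs %% 360)
  # rate follows the elevation estimate
  rate <- azimuth_rate(estimate_elevation(0.8))
  expect_equal(update_tcl_prefs(prefs, 0.8, 1), (prefs + rate) %% 360)
  # tau giving a 36 deg elevation estimate advances 10 deg per hour
  tau36 <- (2.855 - sin(-45 * pi / 180)) / 3.5
  expect_equal(estimate_elevation(tau36), 36, tolerance = 1e-9)
  expect_equal(update_tcl_prefs(prefs, tau36, 1), (prefs + 10) %% 360,
               tolerance = 1e-6)
})

test_that("decoded azimuth converges with solar-layer size", {
  arr <- build_dra()
  suns <- data.frame(elevation = c(15, 30, 45, 60),
                     azimuth = c(20, 130, 240, 310))
  est <- sapply(c(8, 16, 64), function(ns) {
    cmp <- calibrate_compass(build_compass(n_sol = ns), arr)
    polcompass:::compass_predict(cmp, arr, suns)$azimuth_est
  })
  expect_lt(max(abs(circ_diff(est[, 1], est[, 2]))), 0.5)
  expect_lt(max(abs(circ_diff(est[, 1], est[, 3]))), 0.5)
})

test_that("clear-sky decoding has no 180-degree aliasing", {
  arr <- build_dra()
  cmp <- calibrate_compass(build_compass(), arr)
  suns <- data.frame(elevation = rep(30, 72), azimuth = seq(0, 355, 5))
  p <- polcompass:::compass_predict(cmp, arr, suns)
  expect_lt(max(angular_error(p$azimuth_true, p$azimuth_est)), 5)
})

test_that("confidence decreases with disturbance", {
  arr <- build_dra()
  cmp <- calibrate_compass(build_compass(), arr)
  suns <- sample_hemisphere(50, seed = 3)
  mean_tau <- sapply(c(0, 0.33, 0.66, 0.99), function(eta) {
    taus <- sapply(1:20, function(s)
      mean(polcompass:::compass_predict(cmp, arr, suns, eta = eta,
                                        seed = s)$tau))
    mean(taus)
  })
  expect_true(all(diff(mean_tau) < 0))
})
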