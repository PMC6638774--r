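test_that("the sensor layout fills the receptive-field cap homogeneously", {
  dra <- build_dra(60, 56)
  expect_equal(dra$n, 60)
  zd <- 90 - dra$units$theta
  expect_true(all(zd <= 28 + 1e-9))
  # fan rule: axis tangential to the concentric ring (mod 180)
  expect_true(all(abs(((dra$units$alpha - (dra$units$phi - 90)) %% 180)) <
                    1e-9))
  # packing: minimum pairwise separation within 30% of the 5.6 deg
  # interommatidial-angle expectation for this density
  seps <- c()
  for (i in 1:59) {
    seps <- c(seps, min(ang_sep(dra$units$theta[i], dra$units$phi[i],
                                dra$units$theta[(i + 1):60],
                                dra$units$phi[(i + 1):60])))
  }
  expect_gt(min(seps), 5.6 * 0.7)
  expect_lt(min(seps), 5.6 * 1.3)

  single <- build_dra(1)
  expect_equal(single$units$theta, 90)
})

test_that("photoreceptor stimuli follow the Malus opponent form", {
  # unpolarised light splits evenly
  s <- photoreceptor_stimulus(list(luminance = 2, dop = 0, aop = 37), 10)
  expect_equal(s$s_par, 1)
  expect_equal(s$s_perp, 1)
  # full polarisation aligned with the axis
  s <- photoreceptor_stimulus(list(luminance = 1, dop = 1, aop = 25), 25)
  expect_equal(s$s_par, 1)
  expect_equal(s$s_perp, 0, tolerance = 1e-12)
  # d = 0.9 aligned: 0.95 / 0.05, matching the bench stimulus example
  s <- photoreceptor_stimulus(list(luminance = 1, dop = 0.9, aop = 0), 0)
  expect_equal(s$s_par, 0.95)
  expect_equal(s$s_perp, 0.05)
  # energy conservation for arbitrary angles
  s <- photoreceptor_stimulus(list(luminance = 3, dop = 0.6, aop = 77), 13)
  expect_equal(s$s_par + s$s_perp, 3)
})

test_that("the opponent unit is luminance-invariant and bounded", {
  expect_equal(pol_unit_response(0.5, 0.5)$r_pol, 0)
  expect_equal(pol_unit_response(0.95, 0.05)$r_pol, 0.6268, tolerance = 1e-4)
  dark <- pol_unit_response(0, 0)
  expect_equal(dark$r_pol, 0)
  expect_true(dark$failed)
  # scaling both channels by any positive constant changes nothing
  for (c_scale in c(1e-6, 0.1, 7, 1e6)) {
    expect_equal(pol_unit_response(0.8 * c_scale, 0.3 * c_scale)$r_pol,
                 pol_unit_response(0.8, 0.3)$r_pol, tolerance = 1e-12)
  }
  # response over e-vector offset is 180-degree periodic with extrema at
  # alignment and orthogonality
  chi <- seq(0, 359, by = 1)
  st <- photoreceptor_stimulus(list(luminance = 1, dop = 0.9, aop = chi), 0)
  r <- pol_unit_response(st$s_par, st$s_perp)$r_pol
  expect_equal(r[1:180], r[181:360], tolerance = 1e-12)
  expect_equal(which.max(r), 1)          # chi = alpha
  expect_equal(chi[which.min(r)] %% 180, 90)  # orthogonal
})

test_that("sense applies disturbance masks exactly and reproducibly", {
  sky <- sky_state(sun_position(30, 200))
  dra <- build_dra()
  p0 <- sense(sky, dra, eta = 0)
  expect_equal(sum(p0$failed), 0)
  expect_true(all(abs(p0$r_pol) <= 1))

  p1 <- sense(sky, dra, eta = 1)
  expect_true(all(p1$failed))
  expect_true(all(p1$r_pol == 0))

  pa <- sense(sky, dra, eta = 0.5, seed = 42)
  pb <- sense(sky, dra, eta = 0.5, seed = 42)
  expect_equal(sum(pa$failed), 30)
  expect_identical(pa$r_pol, pb$r_pol)
  expect_true(all(pa$r_pol[pa$failed] == 0))
})

test_that("yawing the sensor and rotating the sun commute", {
  dra <- build_dra()
  cfg <- sky_config()
  for (dlt in c(25, 130)) {
    base <- sense(sky_state(sun_position(40, 80), cfg),
                  pose_sensor(dra, yaw = 0))
    both <- sense(sky_state(sun_position(40, 80 + dlt), cfg),
                  pose_sensor(dra, yaw = dlt))
    expect_equal(base$r_pol, both$r_pol, tolerance = 1e-9)
  }
})

test_that("the response pattern mirrors about the solar meridian", {
  dra <- build_dra()
  p <- sense(sky_state(sun_position(40, 0)), dra)
  u <- dra$units
  # mirror partner of each unit: azimuth negated
  partner <- sapply(seq_len(dra$n), function(j) {
    which(abs(u$theta - u$theta[j]) < 1e-9 &
            abs(((u$phi + u$phi[j]) %% 360)) < 1e-6 |
          abs(u$theta - u$theta[j]) < 1e-9 &
            abs(((u$phi + u$phi[j]) %% 360) - 360) < 1e-6)[1]
  })
  ok <- !is.na(partner)
  expect_true(mean(ok) > 0.9)  # the staggered layout is mirror-symmetric
  expect_equal(p$r_pol[ok], p$r_pol[partner[ok]], tolerance = 1e-6)
})

test_that("layout round-trips through CSV export", {
  dra <- build_dra(24, 40)
  f <- tempfile(fileext = ".csv")
  export_layout(dra, f)
  back <- import_layout(f)
  expect_equal(back$n, 24)
  expect_equal(back$units$theta, dra$units$theta)
  expect_equal(back$units$alpha, dra$units$alpha)
  unlink(f)
})
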