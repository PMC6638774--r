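test_that("solar ephemeris matches geometric limits and night flagging", {
  # equator, equinox, solar noon: sun near the zenith
  s <- solar_position("2019-03-21", 12.12, 0, 0, tz = 0)
  expect_gt(s$elevation, 88)
  expect_false(s$night)

  # local solar midnight: below the horizon, flagged as night
  s_night <- solar_position("2019-03-21", 0, 0, 0, tz = 0)
  expect_lt(s_night$elevation, 0)
  expect_true(s_night$night)
})

test_that("solar ephemeris agrees with an independent almanac algorithm", {
  cases <- expand.grid(date = c("2018-09-15", "2019-06-21", "2020-12-01"),
                       hour = c(8, 10, 13, 17),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    s <- solar_position(cases$date[i], cases$hour[i], 37.3925, -5.8839,
                        tz = 2)
    o <- almanac_sun(cases$date[i], cases$hour[i], 37.3925, -5.8839, tz = 2)
    expect_lt(abs(s$elevation - o$elevation), 0.5)
    expect_lt(abs(circ_diff(s$azimuth, o$azimuth)), 0.5)
  }
})

test_that("degree of polarisation follows the Rayleigh profile", {
  sky <- sky_state(sun_position(30, 180), sky_config(d_max = 0.75))
  # gamma = 90: cross-solar point on the solar meridian at elevation 60
  at90 <- sky_sample(sky, 60, 0)
  expect_equal(at90$dop, 0.75, tolerance = 1e-12)
  # gamma = 0: looking at the sun
  at0 <- sky_sample(sky, 30, 180)
  expect_equal(at0$dop, 0, tolerance = 1e-12)
  # gamma = 45: d = 0.75 * 0.5 / 1.5 = 0.25
  at45 <- sky_sample(sky, 75, 180)
  expect_equal(at45$dop, 0.25, tolerance = 1e-9)
  # dome-wide invariants
  grid <- sky_sample(sky, rep(seq(0, 90, 5), each = 36),
                     rep(seq(0, 350, 10), 19))
  expect_true(all(grid$dop >= 0 & grid$dop <= 0.75))
  expect_true(all(grid$aop >= 0 & grid$aop < 180))
  expect_true(all(grid$luminance > 0))
})

test_that("the e-vector is perpendicular to the sun-view great circle", {
  sky <- sky_state(sun_position(35, 120))
  set.seed(11)
  elev <- asin(runif(1000)) * 180 / pi
  az <- runif(1000, 0, 360)
  sm <- sky_sample(sky, elev, az)
  d2r <- pi / 180
  v <- cbind(cos(elev * d2r) * sin(az * d2r),
             cos(elev * d2r) * cos(az * d2r), sin(elev * d2r))
  s <- c(cos(35 * d2r) * sin(120 * d2r), cos(35 * d2r) * cos(120 * d2r),
         sin(35 * d2r))
  # reconstruct the e-vector from the reported local-frame aop
  e_el <- cbind(-sin(elev * d2r) * sin(az * d2r),
                -sin(elev * d2r) * cos(az * d2r), cos(elev * d2r))
  e_az <- cbind(cos(az * d2r), -sin(az * d2r), 0)
  e <- cos(sm$aop * d2r) * e_el + sin(sm$aop * d2r) * e_az
  # tangent of the great circle towards the sun at each view point
  t_gc <- matrix(s, 1000, 3, byrow = TRUE) - v * drop(v %*% s)
  nt <- sqrt(rowSums(t_gc^2))
  keep <- nt > 1e-6
  dots <- abs(rowSums(e * t_gc)[keep] / nt[keep])
  expect_lt(max(dots), 1e-9)
})

test_that("d depends only on the angular distance from the sun", {
  sky <- sky_state(sun_position(50, 10))
  # equal-gamma points on either side of the sun along its meridian
  smA <- sky_sample(sky, 20, 10)    # gamma = 30, below the sun
  smB <- sky_sample(sky, 80, 10)    # gamma = 30, above the sun
  expect_equal(smA$dop, smB$dop, tolerance = 1e-9)
  # and off-meridian points at matched angular distance
  set.seed(3)
  for (k in 1:20) {
    el <- runif(1, 0, 90); az <- runif(1, 0, 360)
    g <- ang_sep(el, az, 50, 10)
    ref <- sky_sample(sky, el, az)
    expect_equal(ref$dop, 0.75 * sin(g * pi / 180)^2 /
                   (1 + cos(g * pi / 180)^2), tolerance = 1e-9)
  }
})

test_that("hemisphere sampling is quasi-uniform and deterministic", {
  one <- sample_hemisphere(1)
  expect_equal(nrow(one), 1)
  expect_true(one$elevation >= 0 && one$elevation <= 90)

  h <- sample_hemisphere(1000, seed = 5)
  d2r <- pi / 180
  v <- cbind(cos(h$elevation * d2r) * sin(h$azimuth * d2r),
             cos(h$elevation * d2r) * cos(h$azimuth * d2r))
  expect_lt(max(abs(colMeans(v))), 2 / sqrt(1000))

  # nearest-neighbour spacing: low coefficient of variation for a lattice
  h5 <- sample_hemisphere(500, seed = 2)
  nn <- sapply(seq_len(500), function(i) {
    sep <- ang_sep(h5$elevation[i], h5$azimuth[i], h5$elevation[-i],
                   h5$azimuth[-i])
    min(sep)
  })
  expect_lt(stats::sd(nn) / mean(nn), 0.5)

  expect_identical(sample_hemisphere(100, seed = 7),
                   sample_hemisphere(100, seed = 7))
  expect_false(isTRUE(all.equal(sample_hemisphere(100, seed = 7)$azimuth,
                                sample_hemisphere(100, seed = 8)$azimuth)))
})

test_that("skydome raster export has the expected grid and fields", {
  sky <- sky_state(sun_position(30, 180))
  f <- tempfile(fileext = ".csv")
  r <- skydome_raster(sky, elev_step = 10, az_step = 30, file = f)
  expect_true(file.exists(f))
  back <- read.csv(f)
  expect_equal(nrow(back), 10 * 12)
  expect_named(back, c("elevation", "azimuth", "luminance", "dop", "aop"))
  unlink(f)
})
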