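# Sky-dome model: solar ephemeris plus the luminance / degree / angle of
# polarisation field used as input to the sensor array. The polarisation
# pattern is a single-scattering Rayleigh model: the degree of polarisation
# depends only on the angular distance gamma from the sun and peaks at
# gamma = 90 deg, and the e-vector is everywhere perpendicular to the great
# circle through the sun and the view point (concentric rings about the sun).

#' Sun position
#'
#' Light-weight container for a sun position on the sky dome.
#'
#' @param elevation solar elevation in degrees from the horizon. Values below
#'   0 are allowed and flag night (see [solar_position()]).
#' @param azimuth solar azimuth in degrees clockwise from north; wrapped to
#'   `[0, 360)`.
#' @return an object of class `sun_position` with fields `elevation`,
#'   `azimuth` and logical `night`.
#' @export
sun_position <- function(elevation, azimuth) {
  stopifnot(is.numeric(elevation), is.numeric(azimuth),
            length(elevation) == 1L, length(azimuth) == 1L,
            elevation <= 90)
  structure(list(elevation = elevation, azimuth = wrap360(azimuth),
                 night = elevation < 0),
            class = "sun_position")
}

#' @export
print.sun_position <- function(x, ...) {
  cat(sprintf("<sun_position> elevation %.2f deg, azimuth %.2f deg%s\n",
              x$elevation, x$azimuth, if (x$night) " (night)" else ""))
  invisible(x)
}

#' Sky model configuration
#'
#' @param d_max maximum degree of linear polarisation of the simulated sky,
#'   reached 90 degrees from the sun. Default 0.75, a typical clear-sky
#'   maximum (multiple scattering keeps real skies well below the Rayleigh
#'   limit of 1).
#' @param latitude,longitude observer position in degrees (longitude east
#'   positive) for ephemeris mode.
#' @param tz offset of local clock time from UTC in hours.
#' @param date calendar date string `"YYYY-MM-DD"` for ephemeris mode (the
#'   default mid-September date reproduces a 10am solar azimuth of about
#'   104 degrees in Seville, the fieldwork condition the behavioural
#'   experiments emulate).
#' @return an object of class `sky_config`.
#' @export
sky_config <- function(d_max = 0.75, latitude = 37.3925, longitude = -5.8839,
                       tz = 2, date = "2018-09-15") {
  stopifnot(d_max > 0, d_max <= 1, abs(latitude) <= 90)
  structure(list(d_max = d_max, latitude = latitude, longitude = longitude,
                 tz = tz, date = date),
            class = "sky_config")
}

#' Sky state
#'
#' Binds a sun position to a sky configuration; the resulting object maps any
#' view direction on the upper hemisphere to a [sky_sample()].
#'
#' @param sun a [sun_position()].
#' @param cfg a [sky_config()].
#' @return an object of class `sky_state`.
#' @export
sky_state <- function(sun, cfg = sky_config()) {
  stopifnot(inherits(sun, "sun_position"), inherits(cfg, "sky_config"))
  structure(list(sun = sun, cfg = cfg), class = "sky_state")
}

julian_day <- function(year, month, day, hour_utc) {
  a <- floor((14 - month) / 12)
  y <- year + 4800 - a
  m <- month + 12 * a - 3
  jdn <- day + floor((153 * m + 2) / 5) + 365 * y + floor(y / 4) -
    floor(y / 100) + floor(y / 400) - 32045
  jdn + (hour_utc - 12) / 24
}

#' Solar position from date, time and location
#'
#' NOAA-style solar position calculation (geometric, no atmospheric
#' refraction; accuracy well under 0.1 degrees for modern dates, far below
#' the compass error scale).
#'
#' @param date date string `"YYYY-MM-DD"` or a `Date`.
#' @param time local clock time in decimal hours (e.g. `10` or `10.5`) or a
#'   string `"HH:MM"`.
#' @param latitude,longitude observer position in degrees, longitude east
#'   positive.
#' @param tz offset of the local clock from UTC in hours.
#' @return a [sun_position()]; `night` is `TRUE` when the sun is below the
#'   horizon (the elevation is then negative, not an error).
#' @examples
#' solar_position("2019-06-21", 10, 37.3925, -5.8839, tz = 2)
#' @export
solar_position <- function(date, time, latitude, longitude, tz = 0) {
  stopifnot(abs(latitude) <= 90)
  d <- as.Date(date)
  if (is.character(time)) {
    hm <- as.numeric(strsplit(time, ":", fixed = TRUE)[[1]])
    time <- hm[1] + ifelse(length(hm) > 1, hm[2] / 60, 0)
  }
  ymd <- as.integer(strsplit(format(d, "%Y-%m-%d"), "-")[[1]])
  hour_utc <- time - tz
  jd <- julian_day(ymd[1], ymd[2], ymd[3], hour_utc)
  jc <- (jd - 2451545) / 36525

  gmls <- wrap360(280.46646 + jc * (36000.76983 + 0.0003032 * jc))
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  ecc <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  eqctr <- sind(gmas) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sind(2 * gmas) * (0.019993 - 0.000101 * jc) + sind(3 * gmas) * 0.000289
  truelong <- gmls + eqctr
  omega <- 125.04 - 1934.136 * jc
  applong <- truelong - 0.00569 - 0.00478 * sind(omega)
  obliq0 <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 -
    jc * 0.001813))) / 60) / 60
  obliq <- obliq0 + 0.00256 * cosd(omega)
  declin <- asind(sind(obliq) * sind(applong))
  vary <- tand(obliq / 2)^2
  eqtime <- 4 / .D2R * (vary * sind(2 * gmls) - 2 * ecc * sind(gmas) +
    4 * ecc * vary * sind(gmas) * cosd(2 * gmls) -
    0.5 * vary^2 * sind(4 * gmls) - 1.25 * ecc^2 * sind(2 * gmas))

  tst <- (time * 60 + eqtime + 4 * longitude - 60 * tz) %% 1440
  ha <- tst / 4 - 180
  ha[ha < -180] <- ha[ha < -180] + 360
  cos_zen <- sind(latitude) * sind(declin) +
    cosd(latitude) * cosd(declin) * cosd(ha)
  zen <- acosd(cos_zen)
  elev <- 90 - zen
  az_arg <- (sind(latitude) * cos_zen - sind(declin)) /
    (cosd(latitude) * sind(zen))
  az <- if (ha > 0) wrap360(acosd(az_arg) + 180) else wrap360(540 - acosd(az_arg))
  sun_position(elev, az)
}

#' Sample the simulated sky at view directions
#'
#' Evaluates the Rayleigh sky model: with `gamma` the angular distance
#' between the view direction and the sun, the degree of polarisation is
#' `d = d_max * sin(gamma)^2 / (1 + cos(gamma)^2)` (zero towards the sun,
#' maximal and equal to `d_max` exactly at `gamma = 90` deg), the angle of
#' polarisation is perpendicular to the great circle through sun and view
#' point, and the relative luminance is proportional to the Rayleigh phase
#' function `1 + cos(gamma)^2` (any smooth positive field would do: the
#' polarisation-opponent stage is luminance invariant).
#'
#' @param sky a [sky_state()].
#' @param elevation,azimuth view direction(s) in degrees, vectorised;
#'   elevation must be `>= 0`.
#' @return a data frame with columns `elevation`, `azimuth`, `luminance`
#'   (relative radiance, positive), `dop` (fraction in `[0, d_max]`) and
#'   `aop` (e-vector orientation in degrees, axial in `[0, 180)`, measured in
#'   the local frame of the view point from the meridian towards increasing
#'   azimuth). Looking exactly at the sun the angle of polarisation is
#'   undefined; `dop` is 0 there and `aop` is reported as 0 by convention.
#' @export
sky_sample <- function(sky, elevation, azimuth) {
  stopifnot(inherits(sky, "sky_state"), all(elevation >= 0))
  n <- max(length(elevation), length(azimuth))
  elevation <- rep_len(elevation, n)
  azimuth <- rep_len(azimuth, n)
  v <- sph_to_vec(elevation, azimuth)
  s <- drop(sph_to_vec(sky$sun$elevation, sky$sun$azimuth))
  cg <- pmin(1, pmax(-1, drop(v %*% s)))
  dop <- sky$cfg$d_max * (1 - cg^2) / (1 + cg^2)
  lum <- (1 + cg^2) / 2

  # e-vector: unit vector along v x s (perpendicular to the sun-view great
  # circle); expressed in the local (meridian, azimuthal) tangent basis.
  e <- cross3(v, rep(1, n) %o% s)
  ne <- rownorm(e)
  ok <- ne > 1e-12
  e[ok, ] <- e[ok, , drop = FALSE] / ne[ok]
  e_el <- cbind(-sind(elevation) * sind(azimuth),
                -sind(elevation) * cosd(azimuth),
                cosd(elevation))
  e_az <- cbind(cosd(azimuth), -sind(azimuth), 0)
  aop <- ifelse(ok,
                wrap_axial(atan2d(rowSums(e * e_az), rowSums(e * e_el))),
                0)
  data.frame(elevation = elevation, azimuth = azimuth,
             luminance = lum, dop = dop, aop = aop)
}

#' Quasi-uniform directions on the upper hemisphere
#'
#' Fibonacci spiral lattice on the hemisphere: deterministic, quasi-uniform
#' sampling with near-constant nearest-neighbour spacing. The `seed`
#' determines a random rotation of the whole lattice about the zenith so that
#' different seeds give different (but equally homogeneous) sun ensembles.
#'
#' @param n_points number of directions (`>= 1`).
#' @param seed integer seed for the azimuthal rotation, or `NULL` for none.
#' @return a data frame with columns `elevation` and `azimuth` (degrees).
#' @export
sample_hemisphere <- function(n_points, seed = NULL) {
  stopifnot(n_points >= 1)
  i <- seq_len(n_points) - 1
  z <- (i + 0.5) / n_points
  elevation <- asind(z)
  golden <- 360 * (1 - 2 / (1 + sqrt(5)))   # ~137.5 deg
  rot <- if (is.null(seed)) 0 else with_seed(seed, stats::runif(1, 0, 360))
  data.frame(elevation = elevation, azimuth = wrap360(i * golden + rot))
}

#' Export a dome raster of the sky model
#'
#' Regular elevation x azimuth grid of luminance, degree and angle of
#' polarisation, suitable for plotting sky maps or for CSV export.
#'
#' @param sky a [sky_state()].
#' @param elev_step,az_step grid steps in degrees.
#' @param file optional path; when given the raster is written as CSV.
#' @return the raster data frame, invisibly when written to file.
#' @export
skydome_raster <- function(sky, elev_step = 1, az_step = 1, file = NULL) {
  grid <- expand.grid(elevation = seq(0, 90, by = elev_step),
                      azimuth = seq(0, 360 - az_step, by = az_step))
  out <- sky_sample(sky, grid$elevation, grid$azimuth)
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}
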