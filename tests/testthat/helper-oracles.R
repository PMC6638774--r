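# Independent oracles used across the test suite.

# Astronomical-Almanac-style solar position (Michalsky 1988): a second,
# independently derived ephemeris for cross-checking solar_position().
almanac_sun <- function(date, hour_local, latitude, longitude, tz = 0) {
  d2r <- pi / 180
  ymd <- as.integer(strsplit(format(as.Date(date), "%Y-%m-%d"), "-")[[1]])
  hour_utc <- hour_local - tz
  a <- floor((14 - ymd[2]) / 12)
  y <- ymd[1] + 4800 - a
  m <- ymd[2] + 12 * a - 3
  jdn <- ymd[3] + floor((153 * m + 2) / 5) + 365 * y + floor(y / 4) -
    floor(y / 100) + floor(y / 400) - 32045
  n <- jdn + (hour_utc - 12) / 24 - 2451545
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360
  lam <- L + 1.915 * sin(g * d2r) + 0.020 * sin(2 * g * d2r)
  eps <- 23.439 - 0.0000004 * n
  ra <- atan2(cos(eps * d2r) * sin(lam * d2r), cos(lam * d2r)) / d2r
  dec <- asin(sin(eps * d2r) * sin(lam * d2r)) / d2r
  gmst <- (6.697375 + 0.0657098242 * n + hour_utc) %% 24
  lmst <- gmst + longitude / 15
  ha <- ((lmst * 15 - ra + 180) %% 360) - 180
  sin_el <- sin(dec * d2r) * sin(latitude * d2r) +
    cos(dec * d2r) * cos(latitude * d2r) * cos(ha * d2r)
  el <- asin(sin_el) / d2r
  az <- atan2(-sin(ha * d2r) * cos(dec * d2r) * cos(latitude * d2r),
              sin(dec * d2r) - sin(latitude * d2r) * sin_el) / d2r
  list(elevation = el, azimuth = az %% 360)
}

# circular helpers
circ_diff <- function(a, b) ((a - b + 180) %% 360) - 180

# angular separation in degrees between two (elevation, azimuth) directions
ang_sep <- function(el1, az1, el2, az2) {
  d2r <- pi / 180
  cg <- sin(el1 * d2r) * sin(el2 * d2r) +
    cos(el1 * d2r) * cos(el2 * d2r) * cos((az1 - az2) * d2r)
  acos(pmin(1, pmax(-1, cg))) / d2r
}
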