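# Spherical geometry helpers. All public angles in the package are degrees;
# azimuths are measured clockwise from north, elevations from the horizon.
# Cartesian convention: x = east, y = north, z = up, so that a direction with
# elevation e and azimuth a maps to (cos e sin a, cos e cos a, sin e).

.D2R <- pi / 180

sind <- function(x) sin(x * .D2R)
cosd <- function(x) cos(x * .D2R)
tand <- function(x) tan(x * .D2R)
asind <- function(x) asin(pmin(1, pmax(-1, x))) / .D2R
acosd <- function(x) acos(pmin(1, pmax(-1, x))) / .D2R
atan2d <- function(y, x) atan2(y, x) / .D2R

#' Wrap angles to a standard range
#'
#' `wrap360()` wraps to `[0, 360)`, `wrap180()` to `(-180, 180]` (signed
#' angular difference) and `wrap_axial()` to `[0, 180)` for axial quantities
#' such as e-vector orientations, which are equivalent under a 180 deg turn.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of wrapped angles in degrees.
#' @examples
#' wrap360(-10)     # 350
#' wrap180(350)     # -10
#' wrap_axial(190)  # 10
#' @export
wrap360 <- function(x) x %% 360

#' @rdname wrap360
#' @export
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' @rdname wrap360
#' @export
wrap_axial <- function(x) {
  y <- x %% 180
  y[y >= 180] <- 0
  y
}

# elevation/azimuth (degrees) -> unit vectors, rows of an n x 3 matrix
sph_to_vec <- function(elevation, azimuth) {
  cbind(cosd(elevation) * sind(azimuth),
        cosd(elevation) * cosd(azimuth),
        sind(elevation))
}

# n x 3 matrix -> list(elevation, azimuth) in degrees
vec_to_sph <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  list(elevation = asind(v[, 3]),
       azimuth = wrap360(atan2d(v[, 1], v[, 2])))
}

cross3 <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rownorm <- function(v) sqrt(rowSums(v^2))

# Rodrigues rotation matrix for a unit axis (length-3) and angle in degrees.
rotation_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sind(angle) * K + (1 - cosd(angle)) * (K %*% K)
}

# Rotation taking the zenith (0,0,1) to the direction (theta_t, phi_t) with
# zero roll about the new axis; identity when theta_t = 90 (no tilt).
tilt_rotation <- function(theta_t, phi_t) {
  delta <- 90 - theta_t
  if (abs(delta) < 1e-12) return(diag(3))
  target <- drop(sph_to_vec(theta_t, phi_t))
  axis <- drop(cross3(c(0, 0, 1), target))
  rotation_axis_angle(axis, delta)
}

# Yaw rotation about the zenith; positive yaw turns the sensor clockwise
# (viewed from above), i.e. adds `yaw` to the azimuth of every direction.
yaw_rotation <- function(yaw) {
  matrix(c(cosd(yaw), -sind(yaw), 0,
           sind(yaw), cosd(yaw), 0,
           0, 0, 1), 3, 3)
}

# Deterministic 32-bit FNV-1a hash of a character string, reduced to a
# positive integer seed. Used to derive independent named sub-streams from a
# master seed so that e.g. terrain draws do not perturb sun sampling.
str_hash32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  h
}

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic components draw their seeds through named sub-streams of a
#' single master seed, so that changing e.g. the disturbance stream leaves sun
#' sampling untouched.
#'
#' @param seed master seed (integer) or `NULL` for non-reproducible runs.
#' @param stream character name of the sub-stream.
#' @param index optional integer index within the stream.
#' @return an integer seed in `[0, 2^31)`, or `NULL` if `seed` is `NULL`.
#' @export
derive_seed <- function(seed, stream, index = 0L) {
  if (is.null(seed)) return(NULL)
  h <- str_hash32(paste0(stream, ":", as.integer(index)))
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
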