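# Cyclopic dorsal-rim sensor array: n polarisation-opponent units placed
# quasi-homogeneously within a spherical cap about the sensor zenith, each
# with a polariser axis tangential to its concentric ring (the fan-like
# arrangement of the ant dorsal rim area). Units point-sample the sky along
# their optical axis; the acceptance angle rho is kept as metadata since it
# is far below the angular scale of the sky pattern.

#' Build the dorsal-rim sensor array
#'
#' Places `n` units on concentric rings inside the cap of angular radius
#' `omega / 2` about the sensor zenith. Ring spacing follows the
#' homogeneous-packing expectation for the cap area, ring populations are
#' proportional to ring circumference, and each unit's polariser axis is
#' tangential to its ring: `alpha = phi - 90` degrees (axial).
#'
#' @param n number of units (default 60, the desert-ant-inspired value).
#' @param omega receptive field of the whole array in degrees (default 56;
#'   all units then lie within 28 degrees of the zenith).
#' @param rho acceptance angle of a single unit in degrees (metadata).
#' @return an object of class `sensor_array`: a list with `n`, `omega`,
#'   `rho`, a `units` data frame (columns `j`, `theta` = elevation in the
#'   sensor frame, `phi` = azimuth, `alpha` = polariser axis) and a `pose`
#'   (`theta_t`, `phi_t`, `yaw`), initially untilted.
#' @examples
#' dra <- build_dra()
#' range(90 - dra$units$theta)  # zenith distances, all <= 28
#' @export
build_dra <- function(n = 60, omega = 56, rho = 5.4) {
  stopifnot(n >= 1, omega > 0, omega <= 180)
  cap <- omega / 2
  if (n == 1) {
    units <- data.frame(j = 1L, theta = 90, phi = 0, alpha = wrap360(-90))
  } else {
    cap_r <- cap * .D2R
    k_rings <- max(1L, round(sqrt(cap_r^2 * n / (2 * pi * (1 - cos(cap_r))))))
    z <- seq_len(k_rings) * cap / k_rings          # ring zenith distances
    w <- sind(z)
    target <- w / sum(w) * n
    cnt <- floor(target)
    rem <- n - sum(cnt)
    if (rem > 0) {
      bump <- order(target - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[bump] <- cnt[bump] + 1
    }
    theta <- numeric(0); phi <- numeric(0)
    for (k in seq_len(k_rings)) {
      if (cnt[k] == 0) next
      offs <- (k %% 2) * 180 / cnt[k]              # stagger alternate rings
      phi_k <- wrap360(offs + (seq_len(cnt[k]) - 1) * 360 / cnt[k])
      theta <- c(theta, rep(90 - z[k], cnt[k]))
      phi <- c(phi, phi_k)
    }
    units <- data.frame(j = seq_len(n), theta = theta, phi = phi,
                        alpha = wrap360(phi - 90))
  }
  structure(list(n = n, omega = omega, rho = rho, units = units,
                 pose = list(theta_t = 90, phi_t = 0, yaw = 0)),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf(
    "<sensor_array> n = %d units, receptive field %.1f deg, rho = %.1f deg\n",
    x$n, x$omega, x$rho))
  cat(sprintf("  pose: theta_t = %.1f, phi_t = %.1f, yaw = %.1f (delta = %.1f deg)\n",
              x$pose$theta_t, x$pose$phi_t, x$pose$yaw, 90 - x$pose$theta_t))
  invisible(x)
}

#' Pose (tilt and yaw) the sensor array
#'
#' The pose is the rigid rotation taking the sensor zenith to the world
#' direction `(theta_t, phi_t)` with zero roll, composed with a yaw about the
#' sensor's own zenith. The tilt magnitude is `delta = 90 - theta_t`.
#' Ground-truth pose is assumed known to the compass (in the insect, head
#' tilt is available from the ocelli or the visual horizon).
#'
#' @param array a [build_dra()] sensor array.
#' @param theta_t elevation of the tilted sensor zenith in degrees (90 = no
#'   tilt).
#' @param phi_t azimuth of the tilt direction in degrees.
#' @param yaw heading of the sensor in degrees clockwise from north.
#' @return the array with updated pose.
#' @export
pose_sensor <- function(array, theta_t = 90, phi_t = 0, yaw = 0) {
  stopifnot(inherits(array, "sensor_array"),
            theta_t >= 0, theta_t <= 90)
  array$pose <- list(theta_t = theta_t, phi_t = phi_t, yaw = yaw)
  array
}

# World-frame unit view directions and polariser-axis vectors (n x 3 each)
# for the posed array. The axis of unit j is the tangent direction at its
# view point with azimuthal orientation alpha_j (axial).
sensor_world_frame <- function(array) {
  u <- array$units
  az <- u$phi + array$pose$yaw
  v <- sph_to_vec(u$theta, az)
  # tangent basis at each unit: meridian (towards zenith) and azimuthal
  e_el <- cbind(-sind(u$theta) * sind(az), -sind(u$theta) * cosd(az),
                cosd(u$theta))
  e_az <- cbind(cosd(az), -sind(az), 0)
  w <- (u$alpha + array$pose$yaw) - az + 180   # orientation from meridian
  a <- cosd(w) * e_el + sind(w) * e_az
  R <- tilt_rotation(array$pose$theta_t, array$pose$phi_t)
  list(view = v %*% t(R), axis = a %*% t(R))
}

#' Photoreceptor stimulus of one polarisation unit
#'
#' Malus-type response of the two orthogonal photoreceptor channels to
#' partially linearly polarised light: `s_par = Y (1 + d cos 2(chi - alpha)) / 2`
#' and `s_perp = Y (1 - d cos 2(chi - alpha)) / 2`, so `s_par + s_perp = Y`
#' and the modulation is sinusoidal in twice the e-vector offset with
#' amplitude proportional to the degree of polarisation.
#'
#' @param sample a data frame as returned by [sky_sample()] (columns
#'   `luminance`, `dop`, `aop`), or a list with those fields.
#' @param alpha polariser axis of the parallel channel in degrees (axial).
#' @return a list with numeric vectors `s_par` and `s_perp`.
#' @export
photoreceptor_stimulus <- function(sample, alpha) {
  m <- sample$dop * cosd(2 * (sample$aop - alpha))
  list(s_par = sample$luminance * (1 + m) / 2,
       s_perp = sample$luminance * (1 - m) / 2)
}

#' Polarisation-opponent unit response
#'
#' Square-root photoreceptor transform followed by opponent processing:
#' `r = (sqrt(s_par) - sqrt(s_perp)) / (sqrt(s_par) + sqrt(s_perp))`, a
#' luminance-invariant value in `[-1, 1]`. Total darkness
#' (`s_par = s_perp = 0`) yields 0 and marks the unit failed.
#'
#' @param s_par,s_perp non-negative photoreceptor stimuli (vectorised).
#' @return a list with `r_pol` (numeric) and `failed` (logical).
#' @examples
#' pol_unit_response(0.95, 0.05)$r_pol  # 0.6268
#' @export
pol_unit_response <- function(s_par, s_perp) {
  stopifnot(all(s_par >= 0), all(s_perp >= 0))
  rp <- sqrt(s_par); rq <- sqrt(s_perp)
  tot <- rp + rq
  failed <- tot == 0
  r <- ifelse(failed, 0, (rp - rq) / ifelse(failed, 1, tot))
  list(r_pol = r, failed = failed)
}

# Draw a failure mask: exactly round(eta * n) units fail, uniformly at random.
failure_mask <- function(n, eta, seed = NULL) {
  stopifnot(eta >= 0, eta <= 1)
  k <- round(eta * n)
  failed <- rep(FALSE, n)
  if (k > 0) {
    idx <- with_seed(seed, sample.int(n, k))
    failed[idx] <- TRUE
  }
  failed
}

# Core vectorised pipeline: POL responses of a posed array for m sun
# directions at once. sun_vec is m x 3; returns an n x m matrix. The angle
# between the sky e-vector (along v x s) and the unit's polariser axis a is
# computed frame-free via cos(chi - alpha) = ((a x v) . s) / sin(gamma).
pol_response_matrix <- function(array, sun_vec, d_max = 0.75) {
  fr <- sensor_world_frame(array)
  if (is.null(dim(sun_vec))) sun_vec <- matrix(sun_vec, nrow = 1L)
  cg <- fr$view %*% t(sun_vec)                     # n x m, cos(gamma)
  cg <- pmin(pmax(cg, -1), 1)
  sg2 <- 1 - cg^2
  d <- d_max * sg2 / (1 + cg^2)
  b <- cross3(fr$axis, fr$view)                    # (a x v), n x 3
  dt <- b %*% t(sun_vec)                           # ((a x v) . s) = |sin g| cos(chi-alpha)
  c2 <- ifelse(sg2 > 1e-24, 2 * dt^2 / sg2 - 1, 0) # cos 2(chi - alpha)
  m <- d * c2
  # luminance cancels in the opponent stage; use Y = 1
  rp <- sqrt((1 + m) / 2); rq <- sqrt((1 - m) / 2)
  (rp - rq) / (rp + rq)
}

#' Sense the sky with the posed array
#'
#' Computes the POL-neuron response of every unit of the (posed) array to the
#' given sky, then masks a fraction `eta` of units chosen uniformly at random
#' as failed (standing in for clouds, occlusion or sensor fault); failed
#' units report 0.
#'
#' @param sky a [sky_state()].
#' @param array a [build_dra()] array, posed with [pose_sensor()].
#' @param eta disturbance level in `[0, 1]`: fraction of units that fail.
#' @param seed integer seed for the failure mask, or `NULL`.
#' @return an object of class `pol_response`: list with `r_pol` (length-n
#'   numeric in `[-1, 1]`), `failed` (logical mask) and `n`.
#' @export
sense <- function(sky, array, eta = 0, seed = NULL) {
  stopifnot(inherits(sky, "sky_state"), inherits(array, "sensor_array"))
  s <- drop(sph_to_vec(sky$sun$elevation, sky$sun$azimuth))
  r <- drop(pol_response_matrix(array, s, sky$cfg$d_max))
  failed <- failure_mask(array$n, eta, seed)
  r[failed] <- 0
  structure(list(r_pol = r, failed = failed, n = array$n),
            class = "pol_response")
}

#' Export / import the sensor layout
#'
#' Writes the unit table (id, elevation, azimuth, polariser axis, acceptance
#' angle) as CSV, or reads such a table back into a `sensor_array`.
#'
#' @param array a `sensor_array`.
#' @param file path to a CSV file.
#' @return `export_layout()` returns `file` invisibly; `import_layout()`
#'   returns a `sensor_array` with default (untilted) pose.
#' @export
export_layout <- function(array, file) {
  u <- array$units
  utils::write.csv(
    data.frame(j = u$j, theta = u$theta, phi = u$phi, alpha = u$alpha,
               rho = array$rho),
    file, row.names = FALSE)
  invisible(file)
}

#' @rdname export_layout
#' @export
import_layout <- function(file) {
  u <- utils::read.csv(file)
  stopifnot(all(c("j", "theta", "phi", "alpha") %in% names(u)))
  structure(list(n = nrow(u), omega = 2 * max(90 - u$theta),
                 rho = if ("rho" %in% names(u)) u$rho[1] else 5.4,
                 units = u[, c("j", "theta", "phi", "alpha")],
                 pose = list(theta_t = 90, phi_t = 0, yaw = 0)),
            class = "sensor_array")
}
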