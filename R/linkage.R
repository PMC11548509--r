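#' Sensor mounting geometry
#'
#' Describes the side-mounted proximity sensor and the seating setup it
#' observes. The world frame has its origin on the ground directly below the
#' sensor, `x` pointing horizontally from the sensor toward the person and `y`
#' pointing up, so the sensor sits at `(0, lse)`. A scan angle of 0 degrees is
#' the horizontal beam toward the person and -90 degrees points straight down.
#'
#' @param lse Sensor height above ground, mm. The sensor is mounted at thigh
#'   height of a standing person, so `lse` must exceed `lk`.
#' @param lc Stool height, mm.
#' @param lk Ground-to-knee height of the seated person, mm (`lse > lk > lc`).
#' @param scan_min,scan_max Scan fan limits, degrees.
#' @param n_samples Number of beams per sweep (at least 3).
#' @param standoff Horizontal distance from the sensor to the body front
#'   surface when the person is standing, mm.
#' @return An object of class `sts_sensor` (a validated list).
#' @examples
#' sensor_geometry()
#' @export
sensor_geometry <- function(lse = 700, lc = 450, lk = 535,
                            scan_min = -90, scan_max = 90,
                            n_samples = 181, standoff = 300) {
  stopifnot_finite(lse, lc, lk, scan_min, scan_max, n_samples, standoff,
                   what = "sensor geometry")
  if (!(lse > lk && lk > lc && lc > 0)) {
    abort("sensor geometry requires lse > lk > lc > 0",
          class = "sitstand_validation_error")
  }
  if (!(scan_min < scan_max) || n_samples < 3) {
    abort("scan fan requires scan_min < scan_max and n_samples >= 3",
          class = "sitstand_validation_error")
  }
  if (standoff <= 0) {
    abort("standoff must be positive", class = "sitstand_validation_error")
  }
  structure(
    list(lse = lse, lc = lc, lk = lk, scan_min = scan_min,
         scan_max = scan_max, n_samples = as.integer(n_samples),
         standoff = standoff),
    class = "sts_sensor"
  )
}

#' Anthropometric segment lengths
#'
#' Bar lengths of the three-bar linkage (shank ankle-knee, thigh knee-hip,
#' trunk hip-shoulder) plus the segment-length ratios used as a fallback when
#' the scanned surface is too straight to localise joints. The default ratios
#' 0.35/0.35/0.30 of the ankle-shoulder distance follow Japanese body-size
#' reference proportions; the default absolute lengths realise those ratios
#' for a 1300 mm ankle-shoulder span.
#'
#' @param lak,lkh,lhs Segment lengths, mm.
#' @param ankle_height Height of the ankle joint above ground, mm. Used when
#'   validating a knee candidate against a ground-level ankle estimate.
#' @param ratio_ak,ratio_kh,ratio_hs Fallback length ratios; must sum to 1.
#' @param length_tolerance Relative half-width of the accepted band around
#'   each target length during joint validation.
#' @return An object of class `sts_anthro`.
#' @examples
#' anthropometry()
#' @export
anthropometry <- function(lak = 455, lkh = 455, lhs = 390, ankle_height = 80,
                          ratio_ak = 0.35, ratio_kh = 0.35, ratio_hs = 0.30,
                          length_tolerance = 0.2) {
  stopifnot_finite(lak, lkh, lhs, ankle_height, ratio_ak, ratio_kh, ratio_hs,
                   length_tolerance, what = "anthropometry")
  if (any(c(lak, lkh, lhs) <= 0)) {
    abort("segment lengths must be positive", class = "sitstand_validation_error")
  }
  if (abs(ratio_ak + ratio_kh + ratio_hs - 1) > 1e-9) {
    abort("segment ratios must sum to 1", class = "sitstand_validation_error")
  }
  if (length_tolerance <= 0 || ankle_height < 0) {
    abort("length_tolerance must be positive and ankle_height non-negative",
          class = "sitstand_validation_error")
  }
  structure(
    list(lak = lak, lkh = lkh, lhs = lhs, ankle_height = ankle_height,
         ratio_ak = ratio_ak, ratio_kh = ratio_kh, ratio_hs = ratio_hs,
         length_tolerance = length_tolerance),
    class = "sts_anthro"
  )
}

#' Joint angles of the sagittal linkage
#'
#' `theta_a` is the signed deviation of the shank from vertical (positive when
#' the knee is forward of the ankle, i.e. toward the sensor). `theta_k` and
#' `theta_h` are bend angles: 180 degrees minus the interior angle at the knee
#' and hip, so a standing person has `theta_k = theta_h = 0` and ideal sitting
#' has `theta_k = theta_h = 90`.
#'
#' @param theta_a,theta_k,theta_h Angles in degrees; `theta_k` and `theta_h`
#'   must lie in `[0, 180]`.
#' @return A one-row tibble with class `sts_angles`.
#' @export
joint_angles <- function(theta_a = 0, theta_k = 0, theta_h = 0) {
  stopifnot_finite(theta_a, theta_k, theta_h, what = "joint angles")
  if (theta_k < 0 || theta_k > 180 || theta_h < 0 || theta_h > 180) {
    abort("theta_k and theta_h must lie in [0, 180] degrees",
          class = "sitstand_validation_error")
  }
  out <- tibble(theta_a = theta_a, theta_k = theta_k, theta_h = theta_h)
  class(out) <- c("sts_angles", class(out))
  out
}

# Segment direction chain shared by forward kinematics and the simulator.
# Knee flexion rotates the thigh clockwise (hip moves backward, +x), hip
# flexion rotates the trunk counterclockwise (trunk comes back up).
bar_directions <- function(theta_a, theta_k, theta_h) {
  d1 <- c(-sin(deg2rad(theta_a)), cos(deg2rad(theta_a)))
  d2 <- drop(rot2(-theta_k) %*% d1)
  d3 <- drop(rot2(theta_h) %*% d2)
  list(d1 = d1, d2 = d2, d3 = d3)
}

#' Forward kinematics of the three-bar linkage
#'
#' Chains the shank, thigh and trunk bars from a fixed ankle point using the
#' angle conventions of [joint_angles()]. Standing angles (0, 0, 0) stack the
#' bars vertically; the ideal sitting pose (0, 90, 90) puts the thigh
#' horizontal behind the knee and the trunk vertical above the hip.
#'
#' @param angles A data frame with columns `theta_a`, `theta_k`, `theta_h`
#'   (one row), e.g. from [joint_angles()].
#' @param anthro An [anthropometry()] object.
#' @param ankle Length-2 numeric, ankle position in mm (world frame).
#' @return A tibble with columns `joint` (`ankle`, `knee`, `hip`, `shoulder`),
#'   `x`, `y` (mm), of class `sts_pose`; the input angles are kept as the
#'   `angles` attribute.
#' @examples
#' forward_kinematics(joint_angles(0, 90, 90), anthropometry(), c(350, 80))
#' @export
forward_kinematics <- function(angles, anthro = anthropometry(),
                               ankle = c(350, 80)) {
  stopifnot(is.data.frame(angles), nrow(angles) == 1)
  a <- angles$theta_a[1]; k <- angles$theta_k[1]; h <- angles$theta_h[1]
  stopifnot_finite(a, k, h, ankle, what = "pose inputs")
  if (k < 0 || k > 180 || h < 0 || h > 180) {
    abort("theta_k and theta_h must lie in [0, 180] degrees",
          class = "sitstand_validation_error")
  }
  if (ankle[2] < 0) {
    abort("ankle must not be below ground", class = "sitstand_validation_error")
  }
  d <- bar_directions(a, k, h)
  pa <- as.numeric(ankle)
  pk <- pa + anthro$lak * d$d1
  ph <- pk + anthro$lkh * d$d2
  ps <- ph + anthro$lhs * d$d3
  pose <- tibble(
    joint = c("ankle", "knee", "hip", "shoulder"),
    x = c(pa[1], pk[1], ph[1], ps[1]),
    y = c(pa[2], pk[2], ph[2], ps[2])
  )
  attr(pose, "angles") <- tibble(theta_a = a, theta_k = k, theta_h = h)
  attr(pose, "anthro") <- anthro
  class(pose) <- c("sts_pose", class(pose))
  pose
}

#' Joint angles from joint points
#'
#' Inverse of [forward_kinematics()] on its image: recovers the shank tilt
#' via `atan2` and the knee/hip bend angles as 180 degrees minus the interior
#' angle at the joint (inner-product formula).
#'
#' @param pa,pk,ph,ps Length-2 numerics: ankle, knee, hip, shoulder positions
#'   in mm. Alternatively pass a `sts_pose` tibble as `pa` and leave the rest
#'   missing.
#' @return A one-row `sts_angles` tibble.
#' @examples
#' angles_from_points(c(0, 0), c(0, 400), c(400, 400), c(400, 800))
#' @export
angles_from_points <- function(pa, pk, ph, ps) {
  if (is.data.frame(pa) && missing(pk)) {
    stopifnot(nrow(pa) == 4)
    m <- as.matrix(pa[, c("x", "y")])
    ps <- m[4, ]; ph <- m[3, ]; pk <- m[2, ]; pa <- m[1, ]
  }
  pa <- as.numeric(pa); pk <- as.numeric(pk)
  ph <- as.numeric(ph); ps <- as.numeric(ps)
  stopifnot_finite(pa, pk, ph, ps, what = "joint points")
  for (pair in list(list(pa, pk), list(pk, ph), list(ph, ps))) {
    if (vnorm(pair[[2]] - pair[[1]]) < 1e-9) {
      abort("coincident consecutive joint points",
            class = "sitstand_degenerate_geometry")
    }
  }
  d1 <- pk - pa
  theta_a <- rad2deg(atan2(-d1[1], d1[2]))
  theta_k <- 180 - interior_angle(pa, pk, ph)
  theta_h <- 180 - interior_angle(pk, ph, ps)
  joint_angles(theta_a, theta_k, theta_h)
}
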