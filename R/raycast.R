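#' Ray-cast a proximity-sensor sweep over a silhouette
#'
#' Simulates one sensor sweep: for every scan angle the beam from the sensor
#' point `(0, lse)` is intersected with the silhouette polyline (plus a ground
#' segment), the nearest hit gives the range, and zero-mean Gaussian noise of
#' standard deviation `noise_sd` is added. Beams that miss every segment
#' return `NA` -- a miss is data, not an error.
#'
#' @param sil A `sts_silhouette` tibble (or any data frame of `x`, `y`
#'   polyline vertices at positive `x`).
#' @param geom A [sensor_geometry()] object.
#' @param noise_sd Range noise standard deviation, mm. The default 10 mm is
#'   consistent with the slight accuracy loss a scanning range finder shows on
#'   a bench test at these distances.
#' @param seed Optional integer; when given the sweep is deterministic.
#' @param t Time stamp carried on the frame, seconds.
#' @param floor Logical: include the ground as a reflecting segment.
#' @return A tibble with columns `m` (beam index), `alpha_deg` (ascending),
#'   `dist_mm` (`NA` on a miss), of class `sts_scan`, with attributes `t_s`
#'   and `geom`.
#' @examples
#' sil <- body_silhouette(forward_kinematics(joint_angles(0, 0, 0)))
#' raycast_scan(sil, sensor_geometry(), noise_sd = 0)
#' @export
raycast_scan <- function(sil, geom = sensor_geometry(), noise_sd = 10,
                         seed = NULL, t = 0, floor = TRUE) {
  stopifnot(is.data.frame(sil), nrow(sil) >= 2)
  alphas <- seq(geom$scan_min, geom$scan_max, length.out = geom$n_samples)
  segs <- cbind(sil$x[-nrow(sil)], sil$y[-nrow(sil)],
                sil$x[-1], sil$y[-1])
  if (floor) segs <- rbind(segs, c(-50, 0, 6000, 0))
  d <- ray_ranges(alphas, c(0, geom$lse), segs)
  if (noise_sd > 0) {
    add_noise <- function() {
      ok <- is.finite(d)
      d[ok] <<- d[ok] + rnorm(sum(ok), 0, noise_sd)
    }
    if (is.null(seed)) add_noise() else withr::with_seed(seed, add_noise())
  }
  out <- tibble(m = seq_along(alphas), alpha_deg = alphas, dist_mm = d)
  attr(out, "t_s") <- t
  attr(out, "geom") <- geom
  class(out) <- c("sts_scan", class(out))
  out
}

# ranges from origin along directions (cos a, sin a) to nearest segment hit;
# segs is a matrix with columns x1, y1, x2, y2. Vectorised over rays x segs.
# Solves origin + s v = seg_start + u e by Cramer's rule.
ray_ranges <- function(alphas_deg, origin, segs) {
  a <- deg2rad(alphas_deg)
  n <- length(a); k <- nrow(segs)
  vx <- cos(a); vy <- sin(a)                     # n rays
  ex <- segs[, 3] - segs[, 1]                    # k segments
  ey <- segs[, 4] - segs[, 2]
  px <- segs[, 1] - origin[1]
  py <- segs[, 2] - origin[2]
  dd <- outer(vx, ey) - outer(vy, ex)            # n x k determinant
  cc <- px * ey - ex * py                        # per-segment constant
  s <- matrix(cc, n, k, byrow = TRUE) / dd       # range along the ray
  u <- (outer(vy, px) - outer(vx, py)) / dd      # position along the segment
  tol <- 1e-9
  hit <- is.finite(s) & s > tol & u >= -tol & u <= 1 + tol
  s[!hit] <- Inf
  d <- apply(s, 1, min)
  d[!is.finite(d)] <- NA_real_
  d
}
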