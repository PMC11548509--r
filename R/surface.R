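#' Convert a polar scan frame to Cartesian points
#'
#' Each return `(alpha_deg, dist_mm)` becomes the world-frame point
#' `(d cos(alpha), lse + d sin(alpha))`: the sensor sits at `(0, lse)`, a
#' 0-degree beam points horizontally toward the person and -90 degrees points
#' straight down. Missed beams (non-finite range) are dropped; the original
#' beam index `m` is kept so scan order is preserved.
#'
#' @param frame A data frame with columns `alpha_deg`, `dist_mm` (and
#'   optionally `m`), e.g. a `sts_scan` from [raycast_scan()].
#' @param geom A [sensor_geometry()]; defaults to the one attached to the
#'   frame.
#' @return A tibble `m`, `alpha_deg`, `x`, `y` ordered by ascending scan
#'   angle.
#' @examples
#' f <- tibble::tibble(alpha_deg = c(-90, 0), dist_mm = c(700, 600))
#' polar_to_points(f, sensor_geometry())
#' @export
polar_to_points <- function(frame, geom = attr(frame, "geom")) {
  stopifnot(is.data.frame(frame))
  if (is.null(geom)) geom <- sensor_geometry()
  if (nrow(frame) == 0) {
    abort("empty scan frame", class = "sitstand_validation_error")
  }
  m <- if ("m" %in% names(frame)) frame$m else seq_len(nrow(frame))
  keep <- is.finite(frame$dist_mm)
  a <- frame$alpha_deg[keep]
  d <- frame$dist_mm[keep]
  tibble(m = m[keep], alpha_deg = a,
         x = d * cos(deg2rad(a)),
         y = geom$lse + d * sin(deg2rad(a)))
}

#' Locate the toe-front point in a scan point cloud
#'
#' Walks the cloud from the first (downward-most) point and returns the index
#' of the first point whose height exceeds the first point's height by more
#' than `rise_tol` -- the front of the toes. Requiring `min_run` consecutive
#' qualifying points rejects single noisy floor returns.
#'
#' @param cloud A point cloud from [polar_to_points()].
#' @param rise_tol Height rise over the first point that counts as body, mm.
#' @param min_run Number of consecutive qualifying points required.
#' @return Integer row index of the toe-front point `pft` in `cloud`.
#' @export
find_toe_front <- function(cloud, rise_tol = 30, min_run = 2L) {
  stopifnot(is.data.frame(cloud), nrow(cloud) >= 1)
  above <- cloud$y > cloud$y[1] + rise_tol
  n <- nrow(cloud)
  for (i in which(above)) {
    run <- i:min(n, i + min_run - 1L)
    if (length(run) == min_run && all(above[run])) return(i)
  }
  abort("no body detected: no point rises above the floor",
        class = "sitstand_no_body")
}

#' Clip the valid body surface from a point cloud
#'
#' Starting at the toe-front point, walks up the cloud in scan order and
#' truncates at the first gap between consecutive points larger than `lsout`
#' (beyond such a jump the returns no longer belong to the body). The last
#' retained point is taken as the shoulder `ps`; the ankle is estimated `lax`
#' behind the toe front at ground height.
#'
#' @param cloud A point cloud from [polar_to_points()].
#' @param toe_idx Row index of the toe front, from [find_toe_front()].
#' @param lax Horizontal toe-to-ankle offset, mm.
#' @param lsout Maximum Euclidean gap between consecutive surface points, mm.
#' @return A tibble of the retained points (`m`, `alpha_deg`, `x`, `y`), class
#'   `sts_surface`, with attributes `pa_est` (ankle estimate, at ground
#'   height) and `pft` (toe-front point).
#' @export
clip_surface <- function(cloud, toe_idx, lax = 120, lsout = 150) {
  stopifnot(is.data.frame(cloud), toe_idx >= 1, toe_idx <= nrow(cloud))
  pts <- cloud[toe_idx:nrow(cloud), , drop = FALSE]
  if (nrow(pts) > 1) {
    gaps <- sqrt(diff(pts$x)^2 + diff(pts$y)^2)
    cut <- which(gaps > lsout)
    if (length(cut)) pts <- pts[seq_len(cut[1]), , drop = FALSE]
  }
  if (nrow(pts) < 4) {
    abort("insufficient body surface after clipping (< 4 points)",
          class = "sitstand_insufficient_surface")
  }
  out <- as_tibble(pts)
  attr(out, "pft") <- c(pts$x[1], pts$y[1])
  attr(out, "pa_est") <- c(pts$x[1] + lax, 0)
  class(out) <- c("sts_surface", class(out))
  out
}
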