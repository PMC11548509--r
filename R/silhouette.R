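#' Sensor-facing body silhouette for a linkage pose
#'
#' Renders the front (sensor-facing) surface of the body as an open polyline:
#' toe tip, instep, then the linkage bars offset toward the sensor by a flesh
#' `thickness`, with mitred corners at the knee and hip. Only the front
#' surface is rendered: the sensor always lies ahead of the person, so the
#' back surface and the arms (kept crossed or at the sides in the motivating
#' protocol) never intersect a beam first.
#'
#' @param pose A `sts_pose` tibble from [forward_kinematics()].
#' @param thickness Forward flesh offset over the linkage, mm (> 0).
#' @param lax Horizontal toe-to-ankle distance, mm: the toe tip sits `lax`
#'   forward of the ankle at ground height.
#' @param toe_rise Height of the instep point just behind the toe tip, mm.
#' @return A tibble with columns `x`, `y` (mm) ordered from toe tip to
#'   shoulder, class `sts_silhouette`.
#' @examples
#' body_silhouette(forward_kinematics(joint_angles(0, 90, 90)))
#' @export
body_silhouette <- function(pose, thickness = 50, lax = 120, toe_rise = 45) {
  stopifnot(is.data.frame(pose), nrow(pose) == 4)
  if (!is.finite(thickness) || thickness <= 0) {
    abort("thickness must be a positive length",
          class = "sitstand_validation_error")
  }
  if (lax <= thickness) {
    abort("lax must exceed thickness", class = "sitstand_validation_error")
  }
  m <- as.matrix(pose[, c("x", "y")])
  pa <- m[1, ]; pk <- m[2, ]; ph <- m[3, ]; ps <- m[4, ]
  bars <- list(list(pa, pk), list(pk, ph), list(ph, ps))
  dirs <- lapply(bars, function(b) unitv(b[[2]] - b[[1]]))
  # sensor-facing normal: of the two perpendiculars, the one pointing
  # front/up (the sensor is at small x, at thigh height)
  normals <- lapply(dirs, function(d) {
    n <- c(-d[2], d[1])
    if (sum(n * c(-1, 1)) < 0) n <- -n
    n
  })
  offset_line <- function(i) list(p = bars[[i]][[1]] + thickness * normals[[i]],
                                  d = dirs[[i]])
  mitre <- function(i, joint) {
    l1 <- offset_line(i); l2 <- offset_line(i + 1L)
    cr <- l1$d[1] * l2$d[2] - l1$d[2] * l2$d[1]
    if (abs(cr) < 1e-9) return(joint + thickness * normals[[i]])
    dp <- l2$p - l1$p
    t1 <- (dp[1] * l2$d[2] - dp[2] * l2$d[1]) / cr
    l1$p + t1 * l1$d
  }
  toe_tip <- c(pa[1] - lax, 0)
  instep <- c(pa[1] - lax + 15, toe_rise)
  ankle_front <- pa + thickness * normals[[1]]
  knee_front <- mitre(1L, pk)
  hip_front <- mitre(2L, ph)
  shoulder_front <- ps + thickness * normals[[3]]
  pts <- rbind(toe_tip, instep, ankle_front, knee_front, hip_front,
               shoulder_front)
  out <- tibble(x = unname(pts[, 1]), y = unname(pts[, 2]))
  attr(out, "thickness") <- thickness
  attr(out, "lax") <- lax
  attr(out, "pose") <- pose
  class(out) <- c("sts_silhouette", class(out))
  out
}
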