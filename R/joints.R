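#' Bend profile of a body surface
#'
#' Computes the turning angle `beta` at every interior surface point: the
#' angle between the incoming and outgoing chords (inner-product formula), 0
#' on a straight stretch and 90 at a right-angle corner. The polyline is
#' optionally smoothed with a centred rolling mean first, which suppresses
#' range noise at the cost of slightly rounding true corners.
#'
#' @param surface A `sts_surface` from [clip_surface()].
#' @param smoothing_window Odd window length in samples; 1 disables smoothing.
#' @param span Chord half-length in samples: the turning angle at `p[i]` is
#'   measured between the chords `p[i-span] -> p[i]` and `p[i] -> p[i+span]`
#'   (clamped near the ends). Spans longer than one sample make the profile
#'   robust to range noise, which otherwise dominates adjacent-chord angles.
#' @return A tibble `i` (interior index), `m`, `x`, `y` (smoothed
#'   coordinates), `beta_deg`, of class `sts_bend`, carrying the smoothed
#'   full polyline as attribute `smoothed`.
#' @export
bend_profile <- function(surface, smoothing_window = 5, span = 8) {
  stopifnot(is.data.frame(surface))
  n <- nrow(surface)
  if (n < 4) {
    abort("bend profile needs at least 4 surface points",
          class = "sitstand_validation_error")
  }
  span <- max(1L, as.integer(span))
  xs <- roll_mean(surface$x, smoothing_window)
  ys <- roll_mean(surface$y, smoothing_window)
  idx <- 2:(n - 1)
  lo <- pmax(idx - span, 1L)
  hi <- pmin(idx + span, n)
  ux <- xs[idx] - xs[lo]; uy <- ys[idx] - ys[lo]
  vx <- xs[hi] - xs[idx]; vy <- ys[hi] - ys[idx]
  lu <- sqrt(ux^2 + uy^2); lv <- sqrt(vx^2 + vy^2)
  if (any(lu < 1e-9) || any(lv < 1e-9)) {
    abort("zero-length chord in surface polyline",
          class = "sitstand_degenerate_geometry")
  }
  dot <- (ux * vx + uy * vy) / (lu * lv)
  beta <- rad2deg(acos(pmax(-1, pmin(1, dot))))
  out <- tibble(i = idx, m = surface$m[idx],
                x = xs[idx], y = ys[idx], beta_deg = beta)
  attr(out, "smoothed") <- tibble(m = surface$m, x = xs, y = ys)
  class(out) <- c("sts_bend", class(out))
  out
}

# retract a surface point into the body by `depth` along the local inward
# normal (perpendicular to the chord through its neighbours); the polyline
# runs toe -> shoulder so the interior lies on its right-hand side
retract_point <- function(poly, idx, depth) {
  n <- nrow(poly)
  lo <- max(1L, idx - 1L); hi <- min(n, idx + 1L)
  chord <- unitv(c(poly$x[hi] - poly$x[lo], poly$y[hi] - poly$y[lo]))
  c(poly$x[idx], poly$y[idx]) + depth * c(chord[2], -chord[1])
}

#' Identify the knee and hip on a body surface
#'
#' Joints are located as curvature maxima of the bend profile: candidate
#' pairs (knee before hip in scan order) are tried in order of decreasing
#' combined bend angle, and a pair is accepted when the implied shank, thigh
#' and trunk lengths all fall within `length_tolerance` of the anthropometric
#' targets (the shank target is measured from the ground because the ankle
#' estimate sits at ground height). When every bend angle is negligible --
#' a near-standing, straight surface -- the knee and hip are instead placed
#' at the 0.35 and 0.70 cumulative fractions of the ankle-shoulder axis,
#' following standard body-proportion ratios. Estimated joints are retracted
#' into the body by `thickness_est` to undo the flesh-surface offset.
#'
#' @param surface A `sts_surface`.
#' @param profile Its [bend_profile()].
#' @param anthro An [anthropometry()].
#' @param flatness Maximum bend angle, degrees, below which the ratio
#'   fallback triggers.
#' @param thickness_est Assumed flesh offset between the scanned surface and
#'   the linkage, mm.
#' @param min_joint_height Candidates below this height are ignored, mm (the
#'   instep corner is a curvature maximum but never a knee).
#' @param max_candidates Number of top-bend candidates searched.
#' @param straight_tol Maximum perpendicular deviation (mm) of the candidate
#'   region from its end-to-end chord below which the surface is treated as
#'   straight. This second fallback trigger is robust to range noise, which
#'   can push individual bend angles well past `flatness` on a truly straight
#'   surface.
#' @return A list of class `sts_joints`: `pose` (tibble of ankle, knee, hip,
#'   shoulder estimates), `angles` (one-row tibble), `method`
#'   (`"bend"` or `"ratio_fallback"`).
#' @export
identify_joints <- function(surface, profile, anthro = anthropometry(),
                            flatness = 10, thickness_est = 50,
                            min_joint_height = 300, max_candidates = 15,
                            straight_tol = 30) {
  poly <- attr(profile, "smoothed")
  pa <- attr(surface, "pa_est")
  n <- nrow(poly)
  ps <- retract_point(poly, n, thickness_est)

  finish <- function(pk, ph, method) {
    pose <- tibble(joint = c("ankle", "knee", "hip", "shoulder"),
                   x = c(pa[1], pk[1], ph[1], ps[1]),
                   y = c(pa[2], pk[2], ph[2], ps[2]))
    structure(list(pose = pose,
                   angles = angles_from_points(pa, pk, ph, ps),
                   method = method),
              class = "sts_joints")
  }

  cand <- profile[profile$y >= min_joint_height, , drop = FALSE]
  chord_dev <- if (nrow(cand) >= 3) {
    e <- unitv(c(cand$x[nrow(cand)] - cand$x[1], cand$y[nrow(cand)] - cand$y[1]))
    max(abs((cand$x - cand$x[1]) * e[2] - (cand$y - cand$y[1]) * e[1]))
  } else Inf
  if (nrow(cand) == 0 || max(cand$beta_deg) < flatness ||
      chord_dev < straight_tol) {
    v <- ps - pa
    return(finish(pa + 0.35 * v, pa + 0.70 * v, "ratio_fallback"))
  }
  cand <- cand[order(-cand$beta_deg, cand$i), , drop = FALSE]
  cand <- head(cand, max_candidates)
  if (nrow(cand) >= 2) {
    pairs <- expand.grid(a = seq_len(nrow(cand)), b = seq_len(nrow(cand)))
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    # knee must come before the hip in scan order
    pairs <- pairs[cand$i[pairs$a] < cand$i[pairs$b], , drop = FALSE]
    score <- cand$beta_deg[pairs$a] + cand$beta_deg[pairs$b]
    pairs <- pairs[order(-score, cand$i[pairs$a]), , drop = FALSE]
    tol <- anthro$length_tolerance
    targets <- c(anthro$lak + anthro$ankle_height, anthro$lkh, anthro$lhs)
    for (r in seq_len(nrow(pairs))) {
      pk <- retract_point(poly, cand$i[pairs$a[r]], thickness_est)
      ph <- retract_point(poly, cand$i[pairs$b[r]], thickness_est)
      lens <- c(vnorm(pk - pa), vnorm(ph - pk), vnorm(ps - ph))
      if (all(abs(lens - targets) <= tol * targets)) {
        return(finish(pk, ph, "bend"))
      }
    }
  }
  abort("no knee/hip candidate pair passed length validation",
        class = "sitstand_estimation_failed")
}

#' Estimate joint angles from a single scan frame
#'
#' Stateless per-frame composition: polar conversion, toe detection, surface
#' clipping, bend profiling, joint identification, angle extraction. Frames
#' on which any stage fails produce a row with `NA` angles and the failure
#' class in `status` rather than an error.
#'
#' @param frame A scan frame (`sts_scan` or data frame with `alpha_deg`,
#'   `dist_mm`).
#' @param config A [pipeline_config()].
#' @param t Time stamp for the output row; defaults to the frame's own.
#' @return A one-row tibble: `t_s`, `theta_a`, `theta_k`, `theta_h`, `pk_x`,
#'   `pk_y`, `ph_x`, `ph_y`, `method`, `status` (`"ok"` or the failure
#'   condition).
#' @export
estimate_frame <- function(frame, config = pipeline_config(), t = NULL) {
  if (is.null(t)) t <- attr(frame, "t_s") %||% NA_real_
  empty <- tibble(t_s = t, theta_a = NA_real_, theta_k = NA_real_,
                  theta_h = NA_real_, pk_x = NA_real_, pk_y = NA_real_,
                  ph_x = NA_real_, ph_y = NA_real_,
                  method = NA_character_, status = "failed")
  tryCatch({
    cloud <- polar_to_points(frame, config$sensor)
    toe <- find_toe_front(cloud, rise_tol = config$rise_tol)
    surf <- clip_surface(cloud, toe, lax = config$lax, lsout = config$lsout)
    prof <- bend_profile(surf, smoothing_window = config$smoothing_window,
                         span = config$bend_span)
    est <- identify_joints(surf, prof, config$anthro,
                           flatness = config$flatness,
                           thickness_est = config$thickness,
                           min_joint_height = config$min_joint_height,
                           straight_tol = config$straight_tol)
    k <- est$pose[est$pose$joint == "knee", ]
    h <- est$pose[est$pose$joint == "hip", ]
    tibble(t_s = t, theta_a = est$angles$theta_a,
           theta_k = est$angles$theta_k, theta_h = est$angles$theta_h,
           pk_x = k$x, pk_y = k$y, ph_x = h$x, ph_y = h$y,
           method = est$method, status = "ok")
  }, sitstand_no_body = function(e) {empty$status <- "no_body"; empty},
  sitstand_insufficient_surface = function(e) {
    empty$status <- "insufficient_surface"; empty},
  sitstand_estimation_failed = function(e) {
    empty$status <- "estimation_failed"; empty},
  sitstand_degenerate_geometry = function(e) {
    empty$status <- "degenerate_geometry"; empty},
  sitstand_validation_error = function(e) {
    empty$status <- "invalid_frame"; empty})
}

#' Estimate joint angles for every frame of a scan log
#'
#' @param scans Long scan tibble (`frame`, `t_s`, `alpha_deg`, `dist_mm`),
#'   e.g. `generate_session()$scans` or a read scan-log CSV.
#' @param config A [pipeline_config()].
#' @return A tibble with one [estimate_frame()] row per frame.
#' @export
estimate_session <- function(scans, config = pipeline_config()) {
  stopifnot(is.data.frame(scans), nrow(scans) > 0)
  if (!"frame" %in% names(scans)) {
    scans$frame <- match(scans$t_s, unique(scans$t_s))
  }
  scans |>
    dplyr::group_by(.data$frame) |>
    dplyr::group_map(function(g, key) {
      estimate_frame(g, config, t = g$t_s[1])
    }) |>
    dplyr::bind_rows()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
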