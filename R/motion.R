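#' Script a stand-up or sit-down motion
#'
#' Defines the time course of a single sit-stand transition for the simulator.
#' Overall progress follows a Gudermannian-type sigmoid
#' `s(t) = (2/pi) * atan(exp(k_speed * (t - b_start)))`, the same
#' accelerate-then-decelerate family used by the distance trajectory model, so
#' motion is slow at both endpoints and fastest at `b_start`. Within that
#' master progress the joint angles move through the field's phase structure:
#' on stand-up the torso leans further forward first (knee fixed), then the
#' whole body extends; on sit-down the body folds first and the torso
#' straightens last. Pauses freeze the pose and stop the progress clock.
#'
#' @param direction `"stand_up"` or `"sit_down"`.
#' @param duration Total scripted time, seconds.
#' @param k_speed Motion-speed parameter, 1/s (maps onto the trajectory
#'   model's `ki`).
#' @param b_start Time of the motion midpoint on the active (non-paused)
#'   clock, seconds (maps onto `bi` as `bi = k_speed * b_start`).
#' @param pauses List of `c(start, length)` pairs in seconds; pauses must lie
#'   inside `[0, duration]` and must not overlap.
#' @param frame_rate Frames per second.
#' @param seed Integer seed used by [generate_session()] for measurement
#'   noise.
#' @param lean Extra forward torso lean beyond the seated 90 degrees, degrees.
#' @param theta_a_sweep Peak forward shank tilt during the body-extension
#'   phase, degrees.
#' @return An object of class `sts_script`.
#' @examples
#' motion_script("stand_up", duration = 8)
#' @export
motion_script <- function(direction = c("stand_up", "sit_down"),
                          duration = 8, k_speed = 2.5, b_start = duration / 2,
                          pauses = list(), frame_rate = 10, seed = 1,
                          lean = 25, theta_a_sweep = 7) {
  direction <- match.arg(direction)
  stopifnot_finite(duration, k_speed, b_start, frame_rate, lean,
                   theta_a_sweep, what = "motion script")
  if (duration <= 0 || k_speed <= 0 || frame_rate <= 0) {
    abort("duration, k_speed and frame_rate must be positive",
          class = "sitstand_validation_error")
  }
  if (length(pauses)) {
    pm <- do.call(rbind, lapply(pauses, as.numeric))
    if (ncol(pm) != 2 || any(pm[, 2] <= 0) ||
        any(pm[, 1] < 0) || any(pm[, 1] + pm[, 2] > duration)) {
      abort("pauses must be (start, length) pairs inside [0, duration]",
            class = "sitstand_validation_error")
    }
    pm <- pm[order(pm[, 1]), , drop = FALSE]
    if (nrow(pm) > 1 &&
        any(pm[-1, 1] < (pm[-nrow(pm), 1] + pm[-nrow(pm), 2]))) {
      abort("pauses must not overlap", class = "sitstand_validation_error")
    }
    pauses <- lapply(seq_len(nrow(pm)), function(i) pm[i, ])
  }
  structure(
    list(direction = direction, duration = duration, k_speed = k_speed,
         b_start = b_start, pauses = pauses, frame_rate = frame_rate,
         seed = as.integer(seed), lean = lean, theta_a_sweep = theta_a_sweep),
    class = "sts_script"
  )
}

# active (non-paused) time elapsed at wall time t; vectorised
active_time <- function(script, t) {
  w <- t
  for (p in script$pauses) {
    w <- w - pmin(pmax(t - p[1], 0), p[2])
  }
  w
}

in_pause <- function(script, t) {
  out <- rep(FALSE, length(t))
  for (p in script$pauses) out <- out | (t >= p[1] & t < p[1] + p[2])
  out
}

# piecewise-linear angle profiles over master progress u in [0, 1]
profile_angles <- function(direction, u, lean, sweep) {
  ramp <- function(u, lo, hi) pmin(pmax((u - lo) / (hi - lo), 0), 1)
  if (direction == "stand_up") {
    # u: 0 = seated, 1 = standing; torso leads (Sa-I), body extends (Sa-II)
    theta_k <- 90 * (1 - ramp(u, 0.25, 1))
    theta_h <- 90 + lean * ramp(u, 0, 0.25) - (90 + lean) * ramp(u, 0.25, 1)
    theta_a <- sweep * ramp(u, 0.25, 0.55) - sweep * ramp(u, 0.55, 1)
  } else {
    # u: 0 = standing, 1 = seated; body folds (Si-I), torso trails (Si-II)
    theta_k <- 90 * ramp(u, 0, 0.75)
    theta_h <- (90 + lean) * ramp(u, 0, 0.75) - lean * ramp(u, 0.75, 1)
    theta_a <- sweep * ramp(u, 0, 0.35) - sweep * ramp(u, 0.35, 0.75)
  }
  tibble(theta_a = theta_a, theta_k = theta_k, theta_h = theta_h)
}

#' Joint angles of a scripted motion at given times
#'
#' @param script A [motion_script()].
#' @param t Numeric vector of times in `[0, duration]`, seconds.
#' @return A tibble with columns `t_s`, `theta_a`, `theta_k`, `theta_h` and
#'   the master progress `u`.
#' @examples
#' script_to_angles(motion_script("stand_up"), c(0, 4, 8))
#' @export
script_to_angles <- function(script, t) {
  stopifnot(inherits(script, "sts_script"))
  if (any(t < -1e-9 | t > script$duration + 1e-9)) {
    abort("t outside [0, duration]", class = "sitstand_range_error")
  }
  w <- active_time(script, t)
  u <- (2 / pi) * atan(exp(script$k_speed * (w - script$b_start)))
  ang <- profile_angles(script$direction, u, script$lean, script$theta_a_sweep)
  dplyr::bind_cols(tibble(t_s = t, u = u), ang)
}

#' Generate a labelled synthetic scan session
#'
#' Runs a [motion_script()] through the forward kinematics, renders the body
#' silhouette per frame and ray-casts noisy sensor sweeps, producing a
#' replayable dataset with per-frame ground truth: exact joint angles, the
#' noise-free distance `lts` on the horizontal beam, and a phase label derived
#' from the script's own angle changes.
#'
#' @param script A [motion_script()].
#' @param anthro An [anthropometry()].
#' @param geom A [sensor_geometry()].
#' @param thickness,lax Silhouette parameters, mm (see [body_silhouette()]).
#' @param noise_sd Range noise, mm; 0 gives bit-identical reruns.
#' @param seed Integer; defaults to the script's seed.
#' @param eps_delta Zero-band used when deriving ground-truth labels from the
#'   script's per-frame angle changes, degrees per frame.
#' @return A list of class `sts_session` with elements `scans` (long tibble:
#'   `frame`, `t_s`, `alpha_deg`, `dist_mm`), `truth` (`t_s`, `theta_a`,
#'   `theta_k`, `theta_h`, `lts_mm`, `phase`), and `calibration` (`lsa_mm`,
#'   `lsi_mm` measured on the endpoint poses).
#' @examples
#' sess <- generate_session(motion_script("stand_up", duration = 2,
#'                                        frame_rate = 5), noise_sd = 0)
#' names(sess)
#' @export
generate_session <- function(script, anthro = anthropometry(),
                             geom = sensor_geometry(), thickness = 50,
                             lax = 120, noise_sd = 10, seed = script$seed,
                             eps_delta = 0.5) {
  stopifnot(inherits(script, "sts_script"))
  hip_sit <- anthro$ankle_height + anthro$lak
  if (abs(hip_sit - geom$lc) > 150) {
    abort(paste0("anthropometry inconsistent with stool height: seated hip ",
                 "height ", hip_sit, " mm vs lc ", geom$lc, " mm"),
          class = "sitstand_configuration_error")
  }
  ankle <- c(geom$standoff + thickness, anthro$ankle_height)
  times <- seq(0, script$duration, by = 1 / script$frame_rate)
  ang <- script_to_angles(script, times)

  cast_true <- function(a, k, h) {
    pose <- forward_kinematics(joint_angles(a, k, h), anthro, ankle)
    sil <- body_silhouette(pose, thickness = thickness, lax = lax)
    raycast_scan(sil, geom, noise_sd = 0, t = 0)
  }
  lsa_true <- measure_lts(cast_true(0, 0, 0), beam_angle = 0)
  lsi_true <- measure_lts(cast_true(0, 90, 90), beam_angle = 0)

  one_frame <- function(i) {
    pose <- forward_kinematics(
      joint_angles(ang$theta_a[i], ang$theta_k[i], ang$theta_h[i]),
      anthro, ankle)
    sil <- body_silhouette(pose, thickness = thickness, lax = lax)
    clean <- raycast_scan(sil, geom, noise_sd = 0, t = times[i])
    lts <- measure_lts(clean, beam_angle = 0)
    d <- clean$dist_mm
    if (noise_sd > 0) {
      ok <- is.finite(d)
      d[ok] <- d[ok] + rnorm(sum(ok), 0, noise_sd)
    }
    list(scan = tibble(frame = i, t_s = times[i], alpha_deg = clean$alpha_deg,
                       dist_mm = d),
         lts = lts)
  }
  frames <- if (is.null(seed)) {
    lapply(seq_along(times), one_frame)
  } else {
    withr::with_seed(seed, lapply(seq_along(times), one_frame))
  }
  scans <- dplyr::bind_rows(lapply(frames, `[[`, "scan"))
  lts_true <- vapply(frames, `[[`, numeric(1), "lts")

  phase <- truth_labels(script, ang, eps_delta)
  truth <- tibble(t_s = times, theta_a = ang$theta_a, theta_k = ang$theta_k,
                  theta_h = ang$theta_h, lts_mm = lts_true, phase = phase)
  structure(
    list(scans = scans, truth = truth,
         calibration = tibble(lsa_mm = lsa_true, lsi_mm = lsi_true),
         script = script, anthro = anthro, geom = geom,
         thickness = thickness, lax = lax, noise_sd = noise_sd),
    class = "sts_session"
  )
}

# ground-truth phase per frame from the script's own angle changes: paused
# frames are HOLD, frames with all per-frame deltas inside the zero-band are
# the adjacent static phase, otherwise the label follows the progress segment.
truth_labels <- function(script, ang, eps_delta) {
  n <- nrow(ang)
  d_max <- c(0, pmax(abs(diff(ang$theta_a)), abs(diff(ang$theta_k)),
                     abs(diff(ang$theta_h))))
  paused <- in_pause(script, ang$t_s)
  u <- ang$u
  up <- script$direction == "stand_up"
  static_lab <- ifelse(u < 0.5,
                       if (up) "Si_III" else "Sa_III",
                       if (up) "Sa_III" else "Si_III")
  dyn_lab <- if (up) ifelse(u <= 0.25, "Sa_I", "Sa_II")
  else ifelse(u <= 0.75, "Si_I", "Si_II")
  lab <- ifelse(paused, "HOLD",
                ifelse(d_max <= eps_delta, static_lab, dyn_lab))
  lab[1] <- static_lab[1]
  factor(lab, levels = phase_levels())
}
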