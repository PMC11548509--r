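#' Phase labels
#'
#' The eight per-frame states: four dynamic phases (`Sa_I` torso flexion,
#' `Sa_II` body extension while rising, `Si_I` downward folding, `Si_II`
#' torso straightening after seat contact), two static phases (`Sa_III`
#' standing, `Si_III` sitting), `HOLD` for a mid-transition pause, and `FALL`
#' for any angle-change pattern no rule explains.
#'
#' @return Character vector of the eight labels, in canonical order.
#' @export
phase_levels <- function() {
  c("Sa_I", "Sa_II", "Sa_III", "Si_I", "Si_II", "Si_III", "HOLD", "FALL")
}

dynamic_levels <- function() c("Sa_I", "Sa_II", "Si_I", "Si_II")

# band sign: 0 inside the zero-band, otherwise the sign
sign_band <- function(x, eps) ifelse(abs(x) <= eps, 0, sign(x))

#' Determine the motion phase of one frame
#'
#' First-match rule cascade over the per-frame angle changes and the tracked
#' beam distance:
#' 1. all three changes inside the zero-band: standing if
#'    `theta_k = theta_h ~ 0` and `lts ~ lsa` (`Sa_III`), sitting if both
#'    angles are near 90 and `lts ~ lsi` (`Si_III`), otherwise a
#'    mid-transition pause (`HOLD`, attributed to the last dynamic phase);
#' 2. knee fixed and hip bending (`d_theta_k = 0`, `d_theta_h > 0`): `Sa_I`;
#' 3. shank and hip moving while the knee extends (`d_theta_a != 0`,
#'    `d_theta_k < 0`, `d_theta_h != 0`): `Sa_II`;
#' 4. shank moving while the knee bends (`d_theta_a != 0`,
#'    `d_theta_k > 0`): `Si_I`;
#' 5. knee fixed and hip extending (`d_theta_k = 0`, `d_theta_h < 0`):
#'    `Si_II`;
#' 6. anything else: `FALL`.
#'
#' Zero-band semantics: the `= 0`, `> 0` and `< 0` tests compare against
#' `eps_delta`, while the `!= 0` tests are literal (any change larger than
#' `eps_nonzero`), because a realistic shank sweep moves far more slowly than
#' the knee and a banded "nonzero" test would starve rule 3 mid-rise.
#'
#' @param d_theta_a,d_theta_k,d_theta_h Angle changes since the previous
#'   frame, degrees.
#' @param theta_k,theta_h Current bend angles, degrees.
#' @param lts Tracked beam distance, mm (`NA` allowed: the static distance
#'   check then fails).
#' @param params A [distance_model_params()] supplying `lsa`/`lsi`.
#' @param prev_dynamic Last dynamic phase seen, or `NA`.
#' @param eps_delta Zero-band half-width, degrees per frame.
#' @param tol_theta Static angle tolerance for the standing test, degrees.
#' @param tol_theta_sit Static angle tolerance for the sitting test, degrees.
#'   Looser than `tol_theta` by default: hip-angle estimates from the front
#'   surface carry a forward-flesh bias of several degrees, and near sitting
#'   the beam distance (insensitive to that bias) disambiguates.
#' @param tol_d Static distance tolerance, mm.
#' @param eps_nonzero Literal-nonzero floor for the `!= 0` tests, degrees.
#' @return A list with `phase` (one of [phase_levels()]), `rule` (integer id,
#'   0 for the first-frame static rule) and `carried` (the dynamic phase a
#'   `HOLD` is attributed to, else `NA`).
#' @export
determine_phase <- function(d_theta_a, d_theta_k, d_theta_h,
                            theta_k, theta_h, lts, params,
                            prev_dynamic = NA_character_,
                            eps_delta = 0.5, tol_theta = 2.5,
                            tol_theta_sit = 10, tol_d = 20,
                            eps_nonzero = 1e-6) {
  sa <- sign_band(d_theta_a, eps_delta)
  sk <- sign_band(d_theta_k, eps_delta)
  sh <- sign_band(d_theta_h, eps_delta)
  nz <- function(x) is.finite(x) && abs(x) > eps_nonzero
  res <- function(phase, rule, carried = NA_character_) {
    list(phase = phase, rule = rule, carried = carried)
  }
  if (sa == 0 && sk == 0 && sh == 0) {
    st <- static_pose(theta_k, theta_h, lts, params, tol_theta, tol_d,
                      tol_theta_sit)
    if (st == "standing") return(res("Sa_III", 1L))
    if (st == "sitting") return(res("Si_III", 1L))
    if (!is.na(prev_dynamic)) return(res("HOLD", 1L, prev_dynamic))
    return(res("FALL", 1L))
  }
  if (sk == 0 && sh > 0) return(res("Sa_I", 2L))
  if (nz(d_theta_a) && sk < 0 && nz(d_theta_h)) return(res("Sa_II", 3L))
  if (nz(d_theta_a) && sk > 0) return(res("Si_I", 4L))
  if (sk == 0 && sh < 0) return(res("Si_II", 5L))
  res("FALL", 6L)
}

static_pose <- function(theta_k, theta_h, lts, params, tol_theta, tol_d,
                        tol_theta_sit = max(tol_theta, 10)) {
  near <- function(x, v, tol) is.finite(x) && abs(x - v) <= tol
  if (near(theta_k, 0, tol_theta) && near(theta_h, 0, tol_theta) &&
      near(lts, params$lsa, tol_d)) return("standing")
  if (near(theta_k, 90, tol_theta_sit) && near(theta_h, 90, tol_theta_sit) &&
      near(lts, params$lsi, tol_d)) return("sitting")
  "neither"
}

#' Run phase determination over a session
#'
#' Applies [determine_phase()] frame by frame over a time-ordered stream of
#' joint angles and beam distances. The angle and distance streams are
#' optionally smoothed with a centred rolling mean before differencing
#' (estimation jitter otherwise leaks into the sign tests), the first frame
#' is classified by the static test alone, and the raw label stream is
#' debounced with a centred rolling mode (ties keep the previous output).
#'
#' @param stream Data frame with columns `t_s`, `theta_a`, `theta_k`,
#'   `theta_h`, `lts_mm` (missing angle rows are linearly interpolated).
#' @param params A [distance_model_params()] supplying `lsa`/`lsi`.
#' @param eps_delta,tol_theta,tol_theta_sit,tol_d,eps_nonzero See
#'   [determine_phase()].
#' @param smooth_window Centred rolling-mean window over the input streams,
#'   frames; 1 disables.
#' @param debounce Centred rolling-mode window over the label stream,
#'   frames; 1 disables.
#' @return A tibble `t_s`, `phase` (factor over [phase_levels()]), `rule_id`,
#'   `carried`.
#' @examples
#' sess <- generate_session(motion_script("stand_up", duration = 3,
#'                                        frame_rate = 5), noise_sd = 0)
#' cal <- sess$calibration
#' run_spd(sess$truth, distance_model_params(cal$lsa_mm, cal$lsi_mm))
#' @export
run_spd <- function(stream, params, eps_delta = 0.5, tol_theta = 2.5,
                    tol_theta_sit = 10, tol_d = 20, eps_nonzero = 1e-6,
                    smooth_window = 1, debounce = 5) {
  stopifnot(is.data.frame(stream),
            all(c("t_s", "theta_a", "theta_k", "theta_h", "lts_mm") %in%
                  names(stream)))
  if (is.unsorted(stream$t_s)) {
    abort("frames must be time-ordered", class = "sitstand_validation_error")
  }
  n <- nrow(stream)
  fill <- function(x) {
    if (all(is.na(x))) return(x)
    if (anyNA(x)) {
      x <- approx(stream$t_s[!is.na(x)], x[!is.na(x)], xout = stream$t_s,
                  rule = 2)$y
    }
    x
  }
  ta <- roll_mean(fill(stream$theta_a), smooth_window)
  tk <- roll_mean(fill(stream$theta_k), smooth_window)
  th <- roll_mean(fill(stream$theta_h), smooth_window)
  lts <- roll_mean(fill(stream$lts_mm), smooth_window)

  phase <- character(n); rule <- integer(n); carried <- rep(NA_character_, n)
  st0 <- static_pose(tk[1], th[1], lts[1], params, tol_theta, tol_d,
                     tol_theta_sit)
  phase[1] <- switch(st0, standing = "Sa_III", sitting = "Si_III", "FALL")
  rule[1] <- 0L
  prev_dyn <- NA_character_
  for (i in seq_len(n)[-1]) {
    r <- determine_phase(ta[i] - ta[i - 1], tk[i] - tk[i - 1],
                         th[i] - th[i - 1], tk[i], th[i], lts[i], params,
                         prev_dynamic = prev_dyn, eps_delta = eps_delta,
                         tol_theta = tol_theta, tol_theta_sit = tol_theta_sit,
                         tol_d = tol_d, eps_nonzero = eps_nonzero)
    phase[i] <- r$phase; rule[i] <- r$rule; carried[i] <- r$carried
    if (r$phase %in% dynamic_levels()) prev_dyn <- r$phase
  }
  phase <- debounce_labels(phase, debounce)
  # re-attribute HOLD frames after debouncing
  last_dyn <- NA_character_
  for (i in seq_len(n)) {
    if (phase[i] %in% dynamic_levels()) last_dyn <- phase[i]
    carried[i] <- if (phase[i] == "HOLD") last_dyn else NA_character_
  }
  tibble(t_s = stream$t_s,
         phase = factor(phase, levels = phase_levels()),
         rule_id = rule, carried = carried)
}

# centred rolling mode; ties resolved toward the previous (already debounced)
# label, then toward the raw centre label
debounce_labels <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  n <- length(x)
  if (window == 1L || n < 3L) return(x)
  h <- (window - 1L) %/% 2L
  out <- x
  for (i in seq_len(n)) {
    w <- x[max(1L, i - h):min(n, i + h)]
    tab <- table(w)
    best <- names(tab)[tab == max(tab)]
    out[i] <- if (x[i] %in% best) {
      x[i]
    } else if (i > 1L && out[i - 1L] %in% best) {
      out[i - 1L]
    } else {
      best[1L]
    }
  }
  out
}
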