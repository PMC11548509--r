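#' Parameters of the Gudermannian distance-trajectory model
#'
#' The sensor-to-body distance on a fixed beam, `lts(t)`, moves between the
#' standing value `lsa` and the sitting value `lsi` along a Gudermannian-type
#' sigmoid:
#' \deqn{l_{ts}(t) = \frac{2}{\pi}(l_{si}-l_{sa})\arctan(e^{-k_i t + b_i}) + l_{sa}}
#' for the standing-up branch, and with exponent `+k_i t - b_i` for the
#' sitting-down branch. `ki` sets the motion speed and `bi` the starting
#' time; both are positive.
#'
#' @param lsa Standing distance, mm (`0 < lsa < lsi`).
#' @param lsi Sitting distance, mm.
#' @param ki Speed constant, 1/s.
#' @param bi Start-time constant, dimensionless.
#' @param branch `"standing"` (stand-up, distance decreasing) or `"sitting"`.
#' @return An object of class `sts_lts_params`.
#' @examples
#' distance_model_params(lsa = 300, lsi = 650, ki = 2, bi = 4)
#' @export
distance_model_params <- function(lsa = 300, lsi = 650, ki = 2, bi = 4,
                                  branch = c("standing", "sitting")) {
  branch <- match.arg(branch)
  stopifnot_finite(lsa, lsi, ki, bi, what = "distance model parameters")
  if (!(lsi > lsa && lsa > 0) || ki <= 0) {
    abort("distance model requires lsi > lsa > 0 and ki > 0",
          class = "sitstand_validation_error")
  }
  structure(list(lsa = lsa, lsi = lsi, ki = ki, bi = bi, branch = branch),
            class = "sts_lts_params")
}

#' Evaluate the distance-trajectory model
#'
#' @param params A [distance_model_params()].
#' @param t Time(s), seconds.
#' @return `lts(t)` in mm, strictly monotone in `t` and bounded in
#'   `(lsa, lsi)`: decreasing on the standing branch, increasing on the
#'   sitting branch.
#' @examples
#' p <- distance_model_params(300, 650, ki = 2, bi = 4)
#' eval_lts(p, p$bi / p$ki)  # midpoint: 475
#' @export
eval_lts <- function(params, t) {
  stopifnot(inherits(params, "sts_lts_params"))
  expo <- if (params$branch == "standing") -params$ki * t + params$bi
  else params$ki * t - params$bi
  (2 / pi) * (params$lsi - params$lsa) * atan(exp(expo)) + params$lsa
}

#' Horizontal displacement of the tracked surface point
#'
#' During the transition the thigh rotates about the knee through a fan angle
#' `theta`; the tracked point's horizontal displacement from its standing
#' position is `Sx = Sy * tan(theta)`, so the beam distance is
#' `lts = lsa + Sx`.
#'
#' @param Sy Vertical distance from the knee to the tracked point, mm.
#' @param theta Fan angle, degrees, in `[0, 90)`.
#' @return `Sx` in mm.
#' @examples
#' sx_from_theta(400, 45)  # 400
#' @export
sx_from_theta <- function(Sy, theta) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta >= 90)) {
    abort("theta must lie in [0, 90) degrees", class = "sitstand_domain_error")
  }
  Sy * tan(deg2rad(theta))
}

#' Measure the tracked-beam distance on a scan frame
#'
#' @param frame Scan frame with `alpha_deg`, `dist_mm`.
#' @param beam_angle Beam used to track the body, degrees; the default 0 is
#'   the horizontal beam at sensor (thigh) height.
#' @return Range of the scan sample nearest `beam_angle`, mm (`NA` if that
#'   beam missed).
#' @export
measure_lts <- function(frame, beam_angle = 0) {
  stopifnot(is.data.frame(frame), nrow(frame) > 0)
  i <- which.min(abs(frame$alpha_deg - beam_angle))
  frame$dist_mm[i]
}

#' Classify a static posture from the beam distance
#'
#' @param lts Measured beam distance(s), mm.
#' @param params A [distance_model_params()] (only `lsa`, `lsi` are used).
#' @param tol_d Distance tolerance, mm.
#' @return Character vector: `"standing"`, `"sitting"` or `"neither"`.
#' @export
classify_static <- function(lts, params, tol_d = 20) {
  dplyr::case_when(
    !is.finite(lts) ~ "neither",
    abs(lts - params$lsa) <= tol_d ~ "standing",
    abs(lts - params$lsi) <= tol_d ~ "sitting",
    TRUE ~ "neither"
  )
}

#' Fit the distance-trajectory model to a measured series
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the Gudermannian model to
#' an observed `(t, lts)` series. Plateau means of the lowest and highest
#' deciles initialise `lsa` and `lsi`; unless fixed via the arguments they are
#' refined together with `ki` and `bi`, since a finite series never quite
#' attains the asymptotes.
#'
#' @param series Data frame with columns `t_s` and `lts_mm`.
#' @param branch `"standing"` or `"sitting"`.
#' @param lsa,lsi Optional fixed asymptotes, mm; `NULL` (default) estimates
#'   them.
#' @return An object of class `sts_lts_fit` with elements `params`
#'   ([distance_model_params()]), `fit` (the `nls` object), `data`, `rms_mm`.
#'   Supports [tidy()], [glance()], [autoplot()] and `predict()`.
#' @examples
#' p <- distance_model_params(300, 650, ki = 2, bi = 4)
#' d <- tibble::tibble(t_s = seq(0, 6, 0.1), lts_mm = eval_lts(p, t_s))
#' fit_lts(d, "standing")$params$ki
#' @export
fit_lts <- function(series, branch = c("standing", "sitting"),
                    lsa = NULL, lsi = NULL) {
  branch <- match.arg(branch)
  stopifnot(is.data.frame(series), all(c("t_s", "lts_mm") %in% names(series)))
  d <- series[is.finite(series$lts_mm) & is.finite(series$t_s), ]
  if (nrow(d) < 8) {
    abort("need at least 8 finite samples to fit the distance model",
          class = "sitstand_fit_failed")
  }
  span <- diff(range(d$lts_mm))
  lo <- mean(sort(d$lts_mm)[seq_len(max(3, nrow(d) %/% 10))])
  hi <- mean(sort(d$lts_mm, decreasing = TRUE)[seq_len(max(3, nrow(d) %/% 10))])
  lsa0 <- lsa %||% lo
  lsi0 <- lsi %||% hi
  if (span < 1 || span < 0.5 * (lsi0 - lsa0)) {
    abort(paste0("series span ", round(span, 1), " mm covers less than half ",
                 "of the standing-sitting range; cannot fit"),
          class = "sitstand_fit_failed")
  }
  # midpoint crossing initialises bi/ki; mid-slope initialises ki
  midv <- (lsa0 + lsi0) / 2
  t_mid <- d$t_s[which.min(abs(d$lts_mm - midv))]
  mid <- d[abs(d$lts_mm - midv) < 0.2 * (lsi0 - lsa0), ]
  sl <- if (nrow(mid) >= 2 && diff(range(mid$t_s)) > 0) {
    abs(stats::coef(stats::lm(lts_mm ~ t_s, data = mid))[2])
  } else {
    span / max(diff(range(d$t_s)), 1e-6)
  }
  ki0 <- max(pi * sl / max(lsi0 - lsa0, 1), 0.1)
  start <- list(ki = unname(ki0), bi = unname(ki0 * t_mid))
  sgn <- if (branch == "standing") -1 else 1
  free_asym <- is.null(lsa) && is.null(lsi)
  if (free_asym) {
    form <- lts_mm ~ (2 / pi) * (lsi - lsa) *
      atan(exp(sgn * (ki * t_s - bi))) + lsa
    start <- c(start, list(lsa = lsa0, lsi = lsi0))
    lower <- c(ki = 1e-6, bi = -Inf, lsa = 1e-6, lsi = 1e-6)
  } else {
    lsa_f <- lsa %||% lo; lsi_f <- lsi %||% hi
    form <- stats::as.formula(substitute(
      lts_mm ~ (2 / pi) * (LSI - LSA) * atan(exp(sgn * (ki * t_s - bi))) + LSA,
      list(LSA = lsa_f, LSI = lsi_f)), env = environment())
    lower <- c(ki = 1e-6, bi = -Inf)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = d, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(paste0("distance-model fit did not converge: ",
                   conditionMessage(e)),
            class = "sitstand_fit_failed")
    })
  cf <- coef(fit)
  params <- distance_model_params(
    lsa = unname(cf["lsa"] %|na|% (lsa %||% lo)),
    lsi = unname(cf["lsi"] %|na|% (lsi %||% hi)),
    ki = unname(cf["ki"]), bi = unname(cf["bi"]), branch = branch)
  structure(list(params = params, fit = fit, data = d,
                 rms_mm = sqrt(mean(residuals(fit)^2))),
            class = "sts_lts_fit")
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' @export
print.sts_lts_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Gudermannian lts(t) fit [%s branch]\n  lsa = %.1f mm, lsi = %.1f mm, ki = %.3f /s, bi = %.3f\n  RMS residual = %.2f mm over %d samples\n",
    p$branch, p$lsa, p$lsi, p$ki, p$bi, x$rms_mm, nrow(x$data)))
  invisible(x)
}

#' @export
predict.sts_lts_fit <- function(object, t = object$data$t_s, ...) {
  eval_lts(object$params, t)
}

#' Tidy a distance-trajectory fit
#'
#' @param x A `sts_lts_fit`.
#' @param ... Unused.
#' @return One row per model term with `estimate` and `std.error`.
#' @export
tidy.sts_lts_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, "Estimate"],
         std.error = s[, "Std. Error"])
}

#' One-row summary of a distance-trajectory fit
#'
#' @param x A `sts_lts_fit`.
#' @param ... Unused.
#' @export
glance.sts_lts_fit <- function(x, ...) {
  tibble(branch = x$params$branch, lsa_mm = x$params$lsa,
         lsi_mm = x$params$lsi, ki = x$params$ki, bi = x$params$bi,
         rms_mm = x$rms_mm, n = nrow(x$data),
         converged = x$fit$convInfo$isConv)
}
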