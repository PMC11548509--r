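#' Pipeline configuration
#'
#' Bundles the sensor geometry, anthropometry, optional distance-model
#' parameters and all processing tolerances. All lengths are mm, angles
#' degrees, times seconds.
#'
#' @param sensor A [sensor_geometry()].
#' @param anthro An [anthropometry()].
#' @param model Optional [distance_model_params()]; when `NULL` the standing
#'   and sitting distances are calibrated from the session itself.
#' @param thickness Assumed flesh offset between scanned surface and linkage,
#'   mm.
#' @param lax Toe-to-ankle horizontal offset, mm.
#' @param lsout Maximum surface gap, mm.
#' @param rise_tol Toe-detection rise over the floor, mm.
#' @param flatness Bend-angle ceiling that triggers the ratio fallback,
#'   degrees.
#' @param min_joint_height Minimum height of a joint candidate, mm.
#' @param smoothing_window Surface-polyline smoothing window, samples.
#' @param bend_span Chord half-length for the bend profile, samples.
#' @param straight_tol Straight-surface deviation tolerance, mm (see
#'   [identify_joints()]).
#' @param stream_smooth Angle/distance stream smoothing window, frames.
#' @param eps_delta Zero-band for per-frame angle changes, degrees.
#' @param tol_theta Static angle tolerance for standing, degrees (default
#'   `asin(tol_d / lkh)` so the angle and distance static tests agree near
#'   standing).
#' @param tol_theta_sit Static angle tolerance for sitting, degrees.
#' @param tol_d Static distance tolerance, mm.
#' @param debounce Label debounce window, frames.
#' @param beam_angle Tracked beam, degrees.
#' @param seed Session seed.
#' @return An object of class `sts_config`.
#' @export
pipeline_config <- function(sensor = sensor_geometry(),
                            anthro = anthropometry(),
                            model = NULL, thickness = 50, lax = 120,
                            lsout = 150, rise_tol = 30, flatness = 10,
                            min_joint_height = 300, smoothing_window = 5,
                            bend_span = 8, straight_tol = 30,
                            stream_smooth = 5, eps_delta = 0.5,
                            tol_theta = round(rad2deg(asin(min(1, tol_d / anthro$lkh))), 2),
                            tol_theta_sit = 10,
                            tol_d = 20, debounce = 5, beam_angle = 0,
                            seed = 1L) {
  vals <- c(thickness, lax, lsout, rise_tol, flatness, min_joint_height,
            smoothing_window, bend_span, straight_tol, stream_smooth,
            eps_delta, tol_theta,
            tol_theta_sit, tol_d, debounce)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all tolerances must be positive", class = "sitstand_validation_error")
  }
  structure(
    list(sensor = sensor, anthro = anthro, model = model,
         thickness = thickness, lax = lax, lsout = lsout,
         rise_tol = rise_tol, flatness = flatness,
         min_joint_height = min_joint_height,
         smoothing_window = smoothing_window, bend_span = bend_span,
         straight_tol = straight_tol, stream_smooth = stream_smooth,
         eps_delta = eps_delta, tol_theta = tol_theta,
         tol_theta_sit = tol_theta_sit, tol_d = tol_d,
         debounce = debounce, beam_angle = beam_angle,
         seed = as.integer(seed)),
    class = "sts_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' Keys carry explicit unit suffixes (`_mm`, `_deg`, `_s`) and the round trip
#' is lossless.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a `sts_config`.
#' @export
write_pipeline_config <- function(config, path) {
  s <- config$sensor; a <- config$anthro
  out <- list(
    sensor = list(lse_mm = s$lse, lc_mm = s$lc, lk_mm = s$lk,
                  scan_min_deg = s$scan_min, scan_max_deg = s$scan_max,
                  n_samples = s$n_samples, standoff_mm = s$standoff),
    anthro = list(lak_mm = a$lak, lkh_mm = a$lkh, lhs_mm = a$lhs,
                  ankle_height_mm = a$ankle_height, ratio_ak = a$ratio_ak,
                  ratio_kh = a$ratio_kh, ratio_hs = a$ratio_hs,
                  length_tolerance = a$length_tolerance),
    model = if (!is.null(config$model)) {
      m <- config$model
      list(lsa_mm = m$lsa, lsi_mm = m$lsi, ki = m$ki, bi = m$bi,
           branch = m$branch)
    },
    tolerances = list(thickness_mm = config$thickness, lax_mm = config$lax,
                      lsout_mm = config$lsout, rise_tol_mm = config$rise_tol,
                      flatness_deg = config$flatness,
                      min_joint_height_mm = config$min_joint_height,
                      smoothing_window = config$smoothing_window,
                      bend_span = config$bend_span,
                      straight_tol_mm = config$straight_tol,
                      stream_smooth = config$stream_smooth,
                      eps_delta_deg = config$eps_delta,
                      tol_theta_deg = config$tol_theta,
                      tol_theta_sit_deg = config$tol_theta_sit,
                      tol_d_mm = config$tol_d, debounce = config$debounce,
                      beam_angle_deg = config$beam_angle),
    seed = config$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort(paste0("malformed configuration file: ", conditionMessage(e)),
          class = "sitstand_configuration_error")
  })
  need <- c("sensor", "anthro", "tolerances", "seed")
  if (!all(need %in% names(y))) {
    abort("configuration file is missing required sections",
          class = "sitstand_configuration_error")
  }
  s <- y$sensor; a <- y$anthro; tl <- y$tolerances
  pipeline_config(
    sensor = sensor_geometry(s$lse_mm, s$lc_mm, s$lk_mm, s$scan_min_deg,
                             s$scan_max_deg, s$n_samples, s$standoff_mm),
    anthro = anthropometry(a$lak_mm, a$lkh_mm, a$lhs_mm, a$ankle_height_mm,
                           a$ratio_ak, a$ratio_kh, a$ratio_hs,
                           a$length_tolerance),
    model = if (!is.null(y$model)) {
      distance_model_params(y$model$lsa_mm, y$model$lsi_mm, y$model$ki,
                            y$model$bi, y$model$branch)
    },
    thickness = tl$thickness_mm, lax = tl$lax_mm, lsout = tl$lsout_mm,
    rise_tol = tl$rise_tol_mm, flatness = tl$flatness_deg,
    min_joint_height = tl$min_joint_height_mm,
    smoothing_window = tl$smoothing_window, bend_span = tl$bend_span,
    straight_tol = tl$straight_tol_mm, stream_smooth = tl$stream_smooth,
    eps_delta = tl$eps_delta_deg, tol_theta = tl$tol_theta_deg,
    tol_theta_sit = tl$tol_theta_sit_deg,
    tol_d = tl$tol_d_mm, debounce = tl$debounce,
    beam_angle = tl$beam_angle_deg, seed = y$seed
  )
}

#' Write / read scan-log and result CSVs
#'
#' Scan logs are long CSVs with one row per (frame, beam): columns `t_s`,
#' `alpha_deg`, `dist_mm`, missed beams written as empty fields. The readers
#' and writers round-trip records exactly.
#'
#' @param scans Long scan tibble (`frame` optional; recreated on read).
#' @param path File path.
#' @export
write_scan_log <- function(scans, path) {
  readr::write_csv(scans[, intersect(c("t_s", "alpha_deg", "dist_mm"),
                                     names(scans))],
                   path, na = "")
  invisible(path)
}

#' @rdname write_scan_log
#' @export
read_scan_log <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    t_s = readr::col_double(), alpha_deg = readr::col_double(),
    dist_mm = readr::col_double()), na = "")
  if (nrow(d) == 0) {
    abort("empty scan log", class = "sitstand_validation_error")
  }
  d$frame <- match(d$t_s, unique(d$t_s))
  d
}

#' Run the full representation pipeline over a scan log
#'
#' Per-frame, in scan order: joint-angle estimation (surface extraction plus
#' joint identification) and tracked-beam distance measurement run in
#' parallel over each sweep; the phase-determination cascade then labels each
#' frame. When no distance model is configured, the standing and sitting
#' distances are calibrated from the lowest and highest stable deciles of the
#' measured beam distances.
#'
#' @param scans A scan-log path or a long scan tibble (`t_s`, `alpha_deg`,
#'   `dist_mm`).
#' @param config A [pipeline_config()] or a path to a YAML configuration.
#' @param out_dir Optional directory; when given, `estimates.csv`, `lts.csv`
#'   and `phases.csv` are written there.
#' @return A list of class `sts_result`: `estimates`, `lts`, `phases`,
#'   `model` (the distance parameters used), `skipped` (frames whose
#'   estimation failed, with status).
#' @export
run_pipeline <- function(scans, config = pipeline_config(), out_dir = NULL) {
  if (is.character(scans)) scans <- read_scan_log(scans)
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(is.data.frame(scans))
  if (nrow(scans) == 0) {
    abort("empty scan log", class = "sitstand_validation_error")
  }
  if (!"frame" %in% names(scans)) {
    scans$frame <- match(scans$t_s, unique(scans$t_s))
  }
  est <- estimate_session(scans, config)
  lts <- scans |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(
      t_s = .data$t_s[1],
      lts_mm = .data$dist_mm[which.min(abs(.data$alpha_deg -
                                             config$beam_angle))],
      .groups = "drop") |>
    dplyr::arrange(.data$t_s)
  model <- config$model
  if (is.null(model)) {
    v <- sort(lts$lts_mm[is.finite(lts$lts_mm)])
    if (length(v) < 10) {
      abort("too few finite beam distances to calibrate lsa/lsi",
            class = "sitstand_configuration_error")
    }
    k <- max(3L, length(v) %/% 10L)
    model <- distance_model_params(lsa = mean(head(v, k)),
                                   lsi = mean(tail(v, k)),
                                   ki = 1, bi = 1)
  }
  stream <- dplyr::left_join(
    est[, c("t_s", "theta_a", "theta_k", "theta_h")],
    lts[, c("t_s", "lts_mm")], by = "t_s")
  phases <- run_spd(stream, model, eps_delta = config$eps_delta,
                    tol_theta = config$tol_theta,
                    tol_theta_sit = config$tol_theta_sit,
                    tol_d = config$tol_d,
                    smooth_window = config$stream_smooth,
                    debounce = config$debounce)
  lts$model_mm <- NA_real_
  lts$residual_mm <- NA_real_
  res <- structure(
    list(estimates = est, lts = lts, phases = phases, model = model,
         skipped = est[est$status != "ok", c("t_s", "status")]),
    class = "sts_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(est, file.path(out_dir, "estimates.csv"), na = "")
    readr::write_csv(lts, file.path(out_dir, "lts.csv"), na = "")
    readr::write_csv(
      dplyr::mutate(phases, phase = as.character(.data$phase)),
      file.path(out_dir, "phases.csv"), na = "")
  }
  res
}

#' @export
print.sts_result <- function(x, ...) {
  ok <- sum(x$estimates$status == "ok")
  cat(sprintf(
    "sit-stand pipeline result: %d frames (%d estimated), lsa = %.0f mm, lsi = %.0f mm\nphases: %s\n",
    nrow(x$estimates), ok, x$model$lsa, x$model$lsi,
    paste(rle(as.character(x$phases$phase))$values, collapse = " -> ")))
  invisible(x)
}

#' Compare a phase stream against ground truth
#'
#' Frame-level confusion matrix over the eight labels plus first-entry timing
#' offsets per phase.
#'
#' @param phases Predicted phases (tibble from [run_spd()] /
#'   [run_pipeline()], or a phases CSV path).
#' @param truth Ground truth (tibble with `t_s`, `phase`, e.g.
#'   `generate_session()$truth`, or a CSV path).
#' @return A list of class `sts_eval`: `confusion` (tibble `truth`, `pred`,
#'   `n`), `timing` (per-phase first-entry times and offset), `accuracy`.
#' @export
evaluate_against_truth <- function(phases, truth) {
  if (is.character(phases)) phases <- readr::read_csv(phases, show_col_types = FALSE)
  if (is.character(truth)) truth <- readr::read_csv(truth, show_col_types = FALSE)
  stopifnot(is.data.frame(phases), is.data.frame(truth))
  lo <- max(min(phases$t_s), min(truth$t_s))
  hi <- min(max(phases$t_s), max(truth$t_s))
  if (lo > hi) {
    abort("phase stream and truth cover disjoint time ranges",
          class = "sitstand_validation_error")
  }
  p <- phases[phases$t_s >= lo & phases$t_s <= hi, ]
  tr <- truth[truth$t_s >= lo & truth$t_s <= hi, ]
  idx <- vapply(p$t_s, function(t) which.min(abs(tr$t_s - t)), integer(1))
  lv <- phase_levels()
  tab <- table(truth = factor(as.character(tr$phase[idx]), levels = lv),
               pred = factor(as.character(p$phase), levels = lv))
  confusion <- as_tibble(tab, .name_repair = "minimal")
  names(confusion) <- c("truth", "pred", "n")
  first_entry <- function(df, col) {
    df |>
      dplyr::mutate(lab = as.character({{ col }})) |>
      dplyr::group_by(.data$lab) |>
      dplyr::summarise(t_first = min(.data$t_s), .groups = "drop")
  }
  timing <- dplyr::full_join(first_entry(tr, .data$phase),
                             first_entry(p, .data$phase),
                             by = "lab", suffix = c("_truth", "_pred")) |>
    dplyr::mutate(offset_s = .data$t_first_pred - .data$t_first_truth) |>
    dplyr::rename(phase = "lab")
  acc <- mean(as.character(tr$phase[idx]) == as.character(p$phase))
  structure(list(confusion = confusion, timing = timing, accuracy = acc),
            class = "sts_eval")
}

#' @export
print.sts_eval <- function(x, ...) {
  cat(sprintf("frame-level accuracy: %.1f%%\n", 100 * x$accuracy))
  agree <- x$confusion[x$confusion$truth == x$confusion$pred & x$confusion$n > 0, ]
  print(agree)
  invisible(x)
}
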