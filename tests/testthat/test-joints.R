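make_surface <- function(x, y) {
  cloud <- tibble::tibble(m = seq_along(x), alpha_deg = seq_along(x), x = x,
                          y = y)
  surf <- tibble::as_tibble(cloud)
  attr(surf, "pa_est") <- c(x[1] + 120, 0)
  attr(surf, "pft") <- c(x[1], y[1])
  class(surf) <- c("sts_surface", class(surf))
  surf
}

test_that("a straight surface has zero bend everywhere", {
  surf <- make_surface(rep(300, 40), seq(40, 1400, length.out = 40))
  prof <- bend_profile(surf, smoothing_window = 1)
  expect_equal(max(prof$beta_deg), 0, tolerance = 1e-9)
})

test_that("a right-angle corner scores a 90-degree bend", {
  # vertical arm, corner vertex, then horizontal arm, 10 mm steps
  x <- c(rep(300, 21), seq(310, 500, 10))
  y <- c(seq(400, 600, 10), rep(600, 20))
  surf <- make_surface(x, y)
  prof <- bend_profile(surf, smoothing_window = 1, span = 8)
  expect_equal(max(prof$beta_deg), 90, tolerance = 1e-6)
  corner <- prof$i[which.max(prof$beta_deg)]
  expect_equal(surf$y[corner], 600, tolerance = 1e-9)
})

test_that("noisy scans localise the knee within two beams", {
  pose <- forward_kinematics(joint_angles(0, 90, 90))
  sil <- body_silhouette(pose)
  g <- sensor_geometry()
  frame <- raycast_scan(sil, g, noise_sd = 10, seed = 5)
  cloud <- polar_to_points(frame)
  surf <- clip_surface(cloud, find_toe_front(cloud))
  prof <- bend_profile(surf, smoothing_window = 5)
  cand <- prof[prof$y >= 300, ]
  best_m <- cand$m[which.max(cand$beta_deg)]
  # beam index of the true knee-front corner
  corner <- c(300, 585)
  alpha_true <- atan2(corner[2] - g$lse, corner[1]) * 180 / pi
  m_true <- which.min(abs(seq(-90, 90, length.out = g$n_samples) - alpha_true))
  expect_lte(abs(best_m - m_true), 2)
})

test_that("the ratio fallback splits a straight surface 0.35/0.35/0.30", {
  surf <- make_surface(rep(300, 60), seq(40, 1390, length.out = 60))
  prof <- bend_profile(surf)
  est <- identify_joints(surf, prof, anthropometry())
  expect_equal(est$method, "ratio_fallback")
  m <- as.matrix(est$pose[, c("x", "y")])
  d <- function(i, j) sqrt(sum((m[i, ] - m[j, ])^2))
  expect_equal(d(1, 2) / d(1, 4), 0.35, tolerance = 1e-9)
  expect_equal(d(3, 4) / d(1, 4), 0.30, tolerance = 1e-9)
  # collinearity of the reconstructed bars
  expect_equal(est$angles$theta_k, 0, tolerance = 1e-6)
  expect_equal(est$angles$theta_h, 0, tolerance = 1e-6)
})

test_that("an ideal sitting scan recovers 90-degree knee and hip bends", {
  est <- estimate_frame(pose_scan(0, 90, 90), pipeline_config())
  expect_equal(est$status, "ok")
  expect_equal(est$theta_k, 90, tolerance = 5)
  expect_equal(est$theta_h, 90, tolerance = 5)
})

test_that("mid-transition poses are recovered within the field tolerance", {
  cfg <- pipeline_config()
  for (k in c(15, 30, 45, 60, 75)) {
    h <- k * 115 / 90            # torso bend coupled to the knee mid-rise
    est <- estimate_frame(pose_scan(5, k, h), cfg)
    expect_equal(est$status, "ok")
    expect_lt(abs(est$theta_k - k), 13)
    expect_lt(abs(est$theta_h - h), 13)
  }
})

test_that("identical frames give identical poses", {
  f <- pose_scan(0, 45, 60)
  e1 <- estimate_frame(f, pipeline_config())
  e2 <- estimate_frame(f, pipeline_config())
  expect_identical(e1, e2)
})

test_that("noisy-session recovery stays within the reported accuracy", {
  sess <- session_up_noisy()
  est <- estimate_session(sess$scans, pipeline_config())
  ok <- est$status == "ok"
  expect_gt(mean(ok), 0.9)
  ek <- abs(est$theta_k - sess$truth$theta_k)[ok]
  eh <- abs(est$theta_h - sess$truth$theta_h)[ok]
  expect_lt(median(ek), 5)
  expect_lte(median(eh), 13)
})

test_that("impossible segment lengths raise an estimation failure", {
  # clear corner, but the body is half scale: lengths fail validation
  x <- c(rep(300, 25), seq(310, 520, 10))
  y <- c(seq(310, 550, 10), rep(560, 22))
  surf <- make_surface(x, y)
  prof <- bend_profile(surf, smoothing_window = 1)
  expect_error(identify_joints(surf, prof, anthropometry()),
               class = "sitstand_estimation_failed")
})

test_that("frame estimation degrades to a status, not an error", {
  g <- sensor_geometry()
  floor_only <- tibble::tibble(alpha_deg = seq(-90, 90, 1),
                               dist_mm = NA_real_)
  floor_only$dist_mm[floor_only$alpha_deg < -45] <-
    g$lse / cos((90 + floor_only$alpha_deg[floor_only$alpha_deg < -45]) *
                  pi / 180)
  est <- estimate_frame(floor_only, pipeline_config())
  expect_true(est$status != "ok")
  expect_true(is.na(est$theta_k))
})
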