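test_that("script endpoints are the sitting and standing poses", {
  s <- motion_script("stand_up", duration = 8)
  a0 <- script_to_angles(s, 0)
  expect_equal(a0$theta_k, 90, tolerance = 0.5)
  expect_equal(a0$theta_h, 90, tolerance = 0.5)
  a1 <- script_to_angles(s, 8)
  expect_equal(a1$theta_k, 0, tolerance = 0.5)
  expect_equal(a1$theta_h, 0, tolerance = 0.5)
  expect_error(script_to_angles(s, 9), class = "sitstand_range_error")
})

test_that("stand-up knee angle is monotone outside pauses", {
  s <- motion_script("stand_up", duration = 8)
  k <- script_to_angles(s, seq(0, 8, 0.01))$theta_k
  expect_true(all(diff(k) <= 1e-9))
})

test_that("pauses freeze the scripted pose", {
  s <- motion_script("stand_up", duration = 10, b_start = 4.5,
                     pauses = list(c(4.8, 1)))
  inside <- script_to_angles(s, seq(4.8, 5.79, 0.1))
  expect_equal(diff(inside$theta_k), rep(0, 9))
  expect_equal(diff(inside$theta_h), rep(0, 9))
  # motion resumes afterwards
  after <- script_to_angles(s, c(5.9, 6.2))
  expect_lt(after$theta_k[2], after$theta_k[1])
})

test_that("pause validation rejects bad intervals", {
  expect_error(motion_script("stand_up", duration = 5,
                             pauses = list(c(4, 2))),
               class = "sitstand_validation_error")
  expect_error(motion_script("stand_up", duration = 8,
                             pauses = list(c(1, 2), c(2, 1))),
               class = "sitstand_validation_error")
})

test_that("ray casting reproduces a vertical wall by trigonometry", {
  wall <- tibble::tibble(x = c(600, 600), y = c(0, 2000))
  g <- sensor_geometry(lse = 700)
  fr <- raycast_scan(wall, g, noise_sd = 0, floor = FALSE)
  expect_equal(fr$dist_mm[fr$alpha_deg == 0], 600)
  expect_equal(fr$dist_mm[fr$alpha_deg == 60], 600 / cos(pi / 3),
               tolerance = 1e-9)
  # rays past the wall top miss
  expect_true(anyNA(fr$dist_mm))
  expect_true(is.na(fr$dist_mm[fr$alpha_deg == 90]))
})

test_that("ray casting is deterministic for a fixed seed", {
  sil <- body_silhouette(forward_kinematics(joint_angles(0, 45, 60)))
  f1 <- raycast_scan(sil, noise_sd = 10, seed = 11)
  f2 <- raycast_scan(sil, noise_sd = 10, seed = 11)
  expect_identical(f1$dist_mm, f2$dist_mm)
  f3 <- raycast_scan(sil, noise_sd = 10, seed = 12)
  expect_false(identical(f1$dist_mm, f3$dist_mm))
})

test_that("silhouette geometry follows the pose", {
  pose <- forward_kinematics(joint_angles(0, 90, 90))
  sil <- body_silhouette(pose, thickness = 50, lax = 120)
  expect_equal(sil$x[1], 350 - 120)          # toe tip lax ahead of the ankle
  expect_equal(sil$y[1], 0)
  expect_true(all(diff(sil$y)[c(1, 2)] > 0)) # rises from the toe
  expect_error(body_silhouette(pose, thickness = -1),
               class = "sitstand_validation_error")
})

test_that("sessions replay bit-identically under a fixed seed", {
  s <- motion_script("stand_up", duration = 1.5, frame_rate = 5, seed = 3)
  a <- generate_session(s, noise_sd = 10)
  b <- generate_session(s, noise_sd = 10)
  expect_identical(a$scans, b$scans)
  expect_identical(a$truth, b$truth)
  c0 <- generate_session(s, noise_sd = 0)
  d0 <- generate_session(s, noise_sd = 0)
  expect_identical(c0$scans, d0$scans)
})

test_that("ranges are bounded below and every frame sees the body", {
  sess <- session_up_clean()
  lo <- sess$geom$standoff - sess$thickness
  by_frame <- split(sess$scans$dist_mm, sess$scans$frame)
  expect_true(all(vapply(by_frame,
                         function(d) all(d[is.finite(d)] >= lo), logical(1))))
  expect_true(all(vapply(by_frame,
                         function(d) any(is.finite(d)), logical(1))))
})

test_that("ground-truth labels of a pause-free stand-up run in order", {
  sess <- session_up_clean()
  runs <- rle(as.character(sess$truth$phase))$values
  expect_identical(runs, c("Si_III", "Sa_I", "Sa_II", "Sa_III"))
  sess2 <- session_down_clean()
  runs2 <- rle(as.character(sess2$truth$phase))$values
  expect_identical(runs2, c("Sa_III", "Si_I", "Si_II", "Si_III"))
})

test_that("inconsistent anthropometry vs stool height is a config error", {
  expect_error(
    generate_session(motion_script("stand_up", duration = 1, frame_rate = 2),
                     anthro = anthropometry(lak = 700),
                     geom = sensor_geometry(lse = 900, lk = 780)),
    class = "sitstand_configuration_error")
})
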