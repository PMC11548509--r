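test_that("standing angles stack the bars vertically", {
  pose <- forward_kinematics(joint_angles(0, 0, 0),
                             anthropometry(400, 400, 400), c(1000, 80))
  expect_equal(pose$x, rep(1000, 4))
  expect_equal(pose$y, c(80, 480, 880, 1280))
})

test_that("ideal sitting puts the thigh horizontal behind the knee", {
  pose <- forward_kinematics(joint_angles(0, 90, 90),
                             anthropometry(400, 400, 400), c(1000, 80))
  m <- as.matrix(pose[, c("x", "y")])
  expect_equal(m[2, ], c(1000, 480), ignore_attr = TRUE)          # knee directly above ankle
  expect_equal(m[3, ], c(1400, 480), ignore_attr = TRUE)          # hip 400 mm behind the knee
  expect_equal(m[4, ], c(1400, 880), ignore_attr = TRUE)          # shoulder 400 mm above the hip
})

test_that("forward kinematics matches an explicit rotation-chain oracle", {
  # independent oracle: chain the three bars with explicit 2x2 matrices
  rot <- function(deg) {
    r <- deg * pi / 180
    matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
  }
  a <- 10; k <- 30; h <- 45
  d1 <- rot(a) %*% c(0, 1)
  d2 <- rot(-k) %*% d1
  d3 <- rot(h) %*% d2
  pa <- c(1000, 80)
  pk <- pa + 420 * drop(d1)
  ph <- pk + 430 * drop(d2)
  ps <- ph + 380 * drop(d3)
  pose <- forward_kinematics(joint_angles(a, k, h),
                             anthropometry(420, 430, 380), pa)
  expect_equal(pose$x, c(pa[1], pk[1], ph[1], ps[1]), tolerance = 1e-9)
  expect_equal(pose$y, c(pa[2], pk[2], ph[2], ps[2]), tolerance = 1e-9)
})

test_that("bar lengths are conserved for arbitrary angles", {
  anthro <- anthropometry(420, 430, 380)
  for (ang in list(c(-15, 10, 170), c(7, 120, 60), c(0, 37.5, 94.2))) {
    pose <- forward_kinematics(joint_angles(ang[1], ang[2], ang[3]), anthro,
                               c(500, 60))
    seg <- sqrt(diff(pose$x)^2 + diff(pose$y)^2)
    expect_equal(seg, c(420, 430, 380), tolerance = 1e-9)
  }
})

test_that("angle extraction inverts forward kinematics over a pose grid", {
  anthro <- anthropometry()
  grid <- expand.grid(a = seq(-20, 20, 10), k = seq(0, 120, 5),
                      h = seq(0, 120, 5))
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    pose <- forward_kinematics(
      joint_angles(grid$a[i], grid$k[i], grid$h[i]), anthro, c(350, 80))
    ang <- angles_from_points(pose)
    worst <- max(worst, abs(ang$theta_a - grid$a[i]),
                 abs(ang$theta_k - grid$k[i]), abs(ang$theta_h - grid$h[i]))
  }
  expect_lt(worst, 1e-6)
})

test_that("collinear and right-angle point sets give the expected angles", {
  up <- angles_from_points(c(0, 0), c(0, 400), c(0, 800), c(0, 1200))
  expect_equal(unlist(up), c(theta_a = 0, theta_k = 0, theta_h = 0))
  sit <- angles_from_points(c(0, 0), c(0, 400), c(400, 400), c(400, 800))
  expect_equal(unlist(sit), c(theta_a = 0, theta_k = 90, theta_h = 90))
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(angles_from_points(c(0, 0), c(0, 0), c(1, 1), c(2, 2)),
               class = "sitstand_degenerate_geometry")
  expect_error(forward_kinematics(joint_angles(0, 0, 0), anthropometry(),
                                  c(NA, 80)),
               class = "sitstand_validation_error")
  expect_error(joint_angles(0, -5, 0), class = "sitstand_validation_error")
  expect_error(anthropometry(ratio_ak = 0.5),
               class = "sitstand_validation_error")
  expect_error(sensor_geometry(lse = 400, lk = 500),
               class = "sitstand_validation_error")
})

test_that("scripted motions carry the expected knee-change signs", {
  up <- script_to_angles(motion_script("stand_up", duration = 8),
                         seq(0, 8, 0.1))
  expect_true(all(diff(up$theta_k) <= 1e-9))   # knee extends while rising
  down <- script_to_angles(motion_script("sit_down", duration = 8),
                           seq(0, 8, 0.1))
  expect_true(all(diff(down$theta_k) >= -1e-9))  # knee bends while sitting
})
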