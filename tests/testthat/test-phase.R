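model_300_650 <- distance_model_params(300, 650, 2, 4)

dp <- function(da, dk, dh, tk = 45, th = 50, lts = 475,
               prev = "Sa_II", m = model_300_650) {
  determine_phase(da, dk, dh, tk, th, lts, m, prev_dynamic = prev)
}

test_that("static, flexion and folding rules fire as documented", {
  r <- dp(0, 0, 0, tk = 0, th = 0, lts = 300)
  expect_equal(r$phase, "Sa_III")
  r <- dp(0, 0, 0, tk = 90, th = 90, lts = 650)
  expect_equal(r$phase, "Si_III")
  expect_equal(dp(0, 0, 3, tk = 85)$phase, "Sa_I")
  expect_equal(dp(2, 4, 1)$phase, "Si_I")
  expect_equal(dp(-2, -4, -3)$phase, "Sa_II")
  expect_equal(dp(0, 0, -3)$phase, "Si_II")
  # knee bending with the shank exactly still matches no rule
  expect_equal(dp(0, 4, 0)$phase, "FALL")
})

test_that("a mid-transition standstill is a HOLD carrying the last phase", {
  r <- dp(0, 0, 0, tk = 45, th = 50, lts = 475, prev = "Sa_II")
  expect_equal(r$phase, "HOLD")
  expect_equal(r$carried, "Sa_II")
  r2 <- dp(0, 0, 0, tk = 45, th = 50, lts = 475, prev = NA)
  expect_equal(r2$phase, "FALL")
})

test_that("every delta pattern maps to exactly one label and the four
          dynamic rules are pairwise disjoint", {
  vals <- c(-2, -0.3, 0, 0.3, 2)   # strict, sub-band, exact-zero signs
  ctx <- list(c(0, 0, 300), c(90, 90, 650), c(45, 50, 475))
  eps <- 0.5
  seen <- character(0)
  for (da in vals) for (dk in vals) for (dh in vals) {
    # direct re-statement of the four dynamic predicates
    band <- function(x) if (abs(x) <= eps) 0 else sign(x)
    nz <- function(x) abs(x) > 1e-6
    fires <- c(band(dk) == 0 && band(dh) > 0,
               nz(da) && band(dk) < 0 && nz(dh),
               nz(da) && band(dk) > 0,
               band(dk) == 0 && band(dh) < 0)
    expect_lte(sum(fires), 1)
    for (cx in ctx) {
      r <- determine_phase(da, dk, dh, cx[1], cx[2], cx[3], model_300_650,
                           prev_dynamic = "Si_I")
      expect_length(r$phase, 1)
      expect_true(r$phase %in% phase_levels())
      seen <- union(seen, r$phase)
    }
  }
  expect_setequal(seen, phase_levels())
  expect_length(setdiff(seen, c("HOLD", "FALL")), 6)
})

test_that("phase streams of clean sessions run in the canonical order", {
  sess <- session_up_clean()
  cal <- sess$calibration
  m <- distance_model_params(cal$lsa_mm, cal$lsi_mm, 2, 4)
  ph <- run_spd(sess$truth, m)
  expect_identical(rle(as.character(ph$phase))$values,
                   c("Si_III", "Sa_I", "Sa_II", "Sa_III"))
  sess2 <- session_down_clean()
  ph2 <- run_spd(sess2$truth, m)
  expect_identical(rle(as.character(ph2$phase))$values,
                   c("Sa_III", "Si_I", "Si_II", "Si_III"))
})

test_that("a mid-rise pause is absorbed as HOLD, never FALL", {
  s <- motion_script("stand_up", duration = 10, b_start = 4.5,
                     pauses = list(c(4.8, 1)))
  sess <- generate_session(s, noise_sd = 0)
  cal <- sess$calibration
  m <- distance_model_params(cal$lsa_mm, cal$lsi_mm, 2, 4)
  ph <- run_spd(sess$truth, m)
  expect_false(any(ph$phase == "FALL"))
  holds <- ph[ph$phase == "HOLD", ]
  expect_gt(nrow(holds), 3)
  expect_true(all(holds$carried == "Sa_II"))
  # HOLD frames only ever follow a dynamic phase
  idx <- which(ph$phase == "HOLD")
  before <- as.character(ph$phase[pmin(idx - 1, nrow(ph))])
  expect_true(all(before %in% c("Sa_II", "HOLD")))
})

test_that("the first frame is classified by the static test alone", {
  m <- model_300_650
  st <- tibble::tibble(t_s = 0:1 / 10, theta_a = 0, theta_k = c(0, 0),
                       theta_h = 0, lts_mm = 300)
  expect_equal(as.character(run_spd(st, m, debounce = 1)$phase[1]), "Sa_III")
  mid <- tibble::tibble(t_s = 0:1 / 10, theta_a = 0, theta_k = 45,
                        theta_h = 45, lts_mm = 475)
  expect_equal(as.character(run_spd(mid, m, debounce = 1)$phase[1]), "FALL")
  expect_error(run_spd(mid[c(2, 1), ], m), class = "sitstand_validation_error")
})

test_that("debouncing removes isolated glitches but keeps real runs", {
  x <- c("Sa_II", "Sa_II", "FALL", "Sa_II", "Sa_II", "Sa_III", "Sa_III")
  expect_false("FALL" %in% sitstand:::debounce_labels(x, 3))
  hold <- rep(c("Sa_II", "HOLD", "Sa_III"), times = c(5, 8, 5))
  expect_identical(sitstand:::debounce_labels(hold, 5), hold)
})
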