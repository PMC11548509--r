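# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# noise-free stand-up session, default study conditions
session_up_clean <- function() {
  fixture("up_clean", function() {
    generate_session(motion_script("stand_up", duration = 8), noise_sd = 0)
  })
}

session_down_clean <- function() {
  fixture("down_clean", function() {
    generate_session(motion_script("sit_down", duration = 8), noise_sd = 0)
  })
}

# 100-frame noisy stand-up session spanning the full sit-stand range
session_up_noisy <- function() {
  fixture("up_noisy", function() {
    generate_session(motion_script("stand_up", duration = 9.9, seed = 42),
                     noise_sd = 10)
  })
}

# noise-free single-pose scan
pose_scan <- function(theta_a, theta_k, theta_h, geom = sensor_geometry()) {
  pose <- forward_kinematics(joint_angles(theta_a, theta_k, theta_h))
  raycast_scan(body_silhouette(pose), geom, noise_sd = 0)
}

default_model <- function() distance_model_params(300, 755, ki = 1, bi = 1)
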