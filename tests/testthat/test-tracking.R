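test_that("triangulation flags degenerate input and separates mixed agents", {
  cams <- camera_rig()
  tracks <- two_agent_tracks()
  det <- project_scene(tracks, cams, pixel_noise_sd = 0)
  t0 <- det$t[1]
  f1 <- det[det$t == t0 & det$truth_id == 1, ]
  f2 <- det[det$t == t0 & det$truth_id == 2, ]
  # mix agent 2's camera-2 detection into agent 1's combination
  obs <- as.matrix(f1[order(f1$camera), c("u", "v")])
  obs_mixed <- obs
  obs_mixed[2, ] <- as.matrix(f2[f2$camera == 2, c("u", "v")])
  err_pure <- triangulate(obs, cams)$error
  err_mixed <- triangulate(obs_mixed, cams)$error
  expect_lt(err_pure, 1e-8)
  expect_gt(err_mixed, 10 * 3)   # far beyond the sigma gate

  expect_error(triangulate(obs[1, , drop = FALSE], cams), "2 cameras")
})

test_that("greedy association equals brute-force assignment on small frames", {
  cams <- camera_rig()
  set.seed(101)
  for (m in 2:3) {
    for (rep in 1:5) {
      tt <- 0
      tracks <- dplyr::bind_rows(lapply(seq_len(m), function(a) {
        tibble::tibble(t = tt, agent = a,
                       x = runif(1, -0.15, 0.15),
                       y = runif(1, -0.15, 0.15),
                       z = runif(1, -0.1, 0.1))
      }))
      det <- project_scene(tracks, cams, pixel_noise_sd = 0.5,
                           seed = 1000 + 10 * m + rep)
      frame <- det[det$t == tt, ]
      if (sum(frame$camera == 1) == 0) next
      got <- associate_frame(frame, cams, sigma = 3)
      want <- brute_force_associate(frame, cams, sigma = 3)
      expect_equal(got$matched, want$matched)
      expect_equal(got$error, want$error, tolerance = 1e-9)
    }
  }
})

test_that("sigma = 0 leaves every detection unmatched", {
  cams <- camera_rig()
  det <- project_scene(two_agent_tracks(), cams, pixel_noise_sd = 0)
  frame <- det[det$t == det$t[1], ]
  out <- associate_frame(frame, cams, sigma = 0)
  expect_false(any(out$matched))
})

test_that("identity recovery on the default scene exceeds 99%", {
  cams <- camera_rig()
  tracks <- two_agent_tracks()
  det <- project_scene(tracks, cams, pixel_noise_sd = 0.5, seed = 7)
  ts <- track_scene(det, cams, sigma = 3)
  # each reconstructed track should carry a single truth identity
  tab <- table(ts$track_id, ts$truth_id)
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gt(purity, 0.99)
  expect_equal(length(unique(ts$track_id)), 2L)
})

test_that("Kalman bridging fills gaps near truth and smoothing keeps delays", {
  # constant-velocity truth with a 3-frame gap
  tt <- seq(0, 2, by = 1 / 60)
  tr <- tibble::tibble(t = tt, x = 0.2 * tt, y = -0.1 * tt, z = 0.05 * tt,
                       valid = TRUE)
  gap <- 61:63
  tr$valid[gap] <- FALSE
  out <- bridge_dropouts(tr, epsilon = 0.2, epsilon_a = 0.8)
  expect_true(all(out$imputed[gap]))
  expect_false(any(out$imputed[-gap]))
  expect_lt(max(abs(out$x[gap] - 0.2 * tt[gap])), 2 * 0.2)

  # enormous measurement noise scale -> filter ignores measurements and
  # free-runs its prediction from the initial state
  curved <- tibble::tibble(t = tt, x = sin(tt), y = 0, z = 0, valid = TRUE)
  ignored <- bridge_dropouts(curved, epsilon = 1e9, epsilon_a = 1e-6)
  # prediction stays near the initial linear extrapolation, not the sine
  expect_gt(max(abs(ignored$x_s - curved$x)), 0.1)

  expect_error(bridge_dropouts(tr[0, ], 0.2, 0.8), "valid")
})

test_that("identification is insensitive to the Kalman noise parameters", {
  # the robustness experiment: bridge transient dropouts with increasing
  # epsilon (epsilon_a held), and check the identified delay does not move
  trial <- make_tracking_trial(eq_example_model("freq"), duration = 4,
                               snr = 20, seed = 31)
  tr <- tibble::tibble(t = trial$t, x = trial$response, y = 0, z = 0,
                       valid = TRUE)
  tr$valid[c(101:103, 220:223, 380:381)] <- FALSE   # transient dropouts
  delays <- vapply(c(0.2, 0.4, 0.6), function(eps) {   # 3x parameter sweep
    br <- bridge_dropouts(tr, epsilon = eps, epsilon_a = 0.8)
    trial_br <- tibble::tibble(t = trial$t, stimulus = trial$stimulus,
                               response = br$x)
    identify_visuomotor(trial_br)$delay_s
  }, 0)
  expect_lt(max(delays) - min(delays), 0.002)
})

test_that("coherence-based role segmentation separates shared from private stimuli", {
  stim <- generate_triangular_stimulus(triangular_schedule(), 4, fs = 120)
  m <- eq_example_model("freq")
  r1 <- simulate_responder(stim, m, snr = 50, seed = 1)
  r2 <- simulate_responder(stim, m, snr = 50, seed = 2)
  # an insect driven by an independent stimulus (different schedule phase)
  stim_b <- generate_triangular_stimulus(
    triangular_schedule(c(1.3, 0.7, 0.35), 0.1), 4, fs = 120)
  r3 <- simulate_responder(stim_b, m, snr = 3, seed = 3)

  tracks <- dplyr::bind_rows(
    tibble::tibble(t = stim$t, track_id = 1, x = r1$value),
    tibble::tibble(t = stim$t, track_id = 2, x = r2$value),
    tibble::tibble(t = stim$t, track_id = 3, x = r3$value)
  )
  roles <- segment_roles(tracks, band_hz = c(0, 5), threshold = 0.6)
  expect_equal(roles$role[roles$track_id %in% c(1, 2)], c("group", "group"))

  solo_only <- segment_roles(tracks[tracks$track_id == 1, ])
  expect_equal(solo_only$role, "solo")
})
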