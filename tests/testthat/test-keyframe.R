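test_that("keyframe count follows the compression-rate formula", {
  expect_equal(compute_k(1.0, 367), 367L)
  expect_equal(compute_k(0.15, 1000), 150L)
  expect_equal(compute_k(0.15, 1517), 228L)  # round-half-up
  expect_equal(compute_k(0.001, 10), 1L)     # clamped to >= 1
  expect_error(compute_k(0, 100), "c_rate")
  expect_error(compute_k(1.2, 100), "c_rate")
})

test_that("interpolation follows the linear blend exactly", {
  p1 <- c(1, 2, 3); p2 <- c(5, 6, 7)
  expect_equal(interpolate_frame(p1, p2, 0, 5, 10), (p1 + p2) / 2)
  expect_equal(interpolate_frame(p1, p2, 0, 1e-9, 10), p1, tolerance = 1e-8)
  expect_equal(interpolate_frame(p1, p2, 0, 2, 10), 0.8 * p1 + 0.2 * p2)
  expect_error(interpolate_frame(p1, p2, 0, 12, 10), "strictly between")
  expect_error(interpolate_frame(p1, p2, 0, 0, 10), "strictly between")
})

test_that("degenerate and full-rate extractions behave as closed forms", {
  # constant motion: reconstruction error must be exactly 0 for any k
  pos <- structure(array(rep(c(1, 2, 3), each = 20),
                         c(10, 2, 3))[rep(1, 10), , , drop = FALSE],
                   class = "position_sequence")
  pos <- structure(array(5, c(12, 2, 3)), class = "position_sequence")
  kf <- extract_keyframes(pos, compression_config(c_rate = 0.3, seed = 1))
  expect_equal(kf$reconstruction_error, 0)

  # full rate keeps every frame
  motion <- smooth_motion(seed = 2, duration = 0.5)
  p <- forward_kinematics(motion)
  kf1 <- extract_keyframes(p, compression_config(c_rate = 1.0))
  expect_equal(kf1$indices, seq_len(n_frames(motion)))
  expect_equal(kf1$reconstruction_error, 0)
})

test_that("two well-separated pose blocks each contribute a keyframe", {
  poseA <- c(0, 0, 0, 10, 0, 0)
  poseB <- c(100, 0, 0, 110, 0, 0)
  arr <- array(0, c(6, 2, 3))
  for (f in 1:3) arr[f, , ] <- matrix(poseA, 2, 3, byrow = TRUE)
  for (f in 4:6) arr[f, , ] <- matrix(poseB, 2, 3, byrow = TRUE)
  pos <- structure(arr, class = "position_sequence")
  kf <- extract_keyframes(pos, compression_config(c_rate = 2 / 6, seed = 5))
  expect_equal(kf$k, 2L)
  expect_true(any(kf$indices <= 3) && any(kf$indices >= 4))
})

test_that("reconstruction error equals the hand-computed posture distance", {
  # all frames constant except one joint displaced by delta mid-sequence
  N <- 9L; delta <- 2.5
  arr <- array(1, c(N, 3, 3))
  arr[5, 2, 1] <- 1 + delta
  pos <- structure(arr, class = "position_sequence")
  kf <- structure(list(k = 2L, indices = c(1L, N),
                       key_positions = arr[c(1, N), , , drop = FALSE],
                       reconstruction_error = NA_real_),
                  class = "keyframe_result")
  expect_equal(reconstruction_error(pos, kf), delta / N)

  # keyframes = all frames -> error 0
  kf_all <- structure(list(k = N, indices = seq_len(N),
                           key_positions = arr,
                           reconstruction_error = NA_real_),
                      class = "keyframe_result")
  expect_equal(reconstruction_error(pos, kf_all), 0)
  expect_error(reconstruction_error(pos, structure(list(indices = integer()),
                                                   class = "keyframe_result")),
               "empty")
})

test_that("reconstruction error is invariant under rigid translation", {
  motion <- smooth_motion(seed = 4, duration = 0.6)
  p <- forward_kinematics(motion)
  cfg <- compression_config(c_rate = 0.2, seed = 9)
  e1 <- extract_keyframes(p, cfg)$reconstruction_error
  shifted <- unclass(p)
  shifted[, , 1] <- shifted[, , 1] + 500
  shifted[, , 2] <- shifted[, , 2] - 120
  e2 <- extract_keyframes(structure(shifted, class = "position_sequence"),
                          cfg)$reconstruction_error
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("extraction is reproducible and sparser keyframes cost more error", {
  motion <- smooth_motion(seed = 6, duration = 1.2)
  p <- forward_kinematics(motion)
  cfg <- compression_config(c_rate = 0.1, seed = 21, kmeans_restarts = 2)
  expect_identical(extract_keyframes(p, cfg)$indices,
                   extract_keyframes(p, cfg)$indices)
  e_low <- extract_keyframes(p, compression_config(2 / n_frames(motion),
                                                   seed = 21))$reconstruction_error
  e_high <- extract_keyframes(p, compression_config(0.5,
                                                    seed = 21))$reconstruction_error
  expect_gte(e_low, e_high)
})

test_that("compression sweep tabulates error against rate", {
  motion <- smooth_motion(seed = 8, duration = 1)
  p <- forward_kinematics(motion)
  sw <- compression_sweep(p, c(0.05, 0.10, 0.15, 0.20, 0.25),
                          compression_config(seed = 2))
  expect_equal(sw$rate, c(0.05, 0.10, 0.15, 0.20, 0.25))
  expect_true(all(diff(sw$error) <= sw$error[-nrow(sw)] * 0.05 + 1e-9))
  expect_equal(compression_sweep(p, numeric(0)),
               data.frame(rate = numeric(), k = integer(), error = numeric()))
  expect_equal(compression_sweep(p, 1.0)$error, 0)
})
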