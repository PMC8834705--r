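test_that("Euler-to-quaternion conversion matches closed forms and the rotation-matrix oracle", {
  expect_equal(unname(euler_to_quaternion(c(0, 0, 0))), c(1, 0, 0, 0))
  expect_equal(unname(euler_to_quaternion(c(pi / 2, 0, 0))),
               c(cos(pi / 4), sin(pi / 4), 0, 0))
  expect_equal(unname(euler_to_quaternion(c(pi / 2, pi / 2, pi / 2))),
               c(sqrt(0.5), 0, sqrt(0.5), 0), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:200) {
    ang <- runif(3, -2 * pi, 2 * pi)
    q <- euler_to_quaternion(ang)
    expect_equal(sum(q^2), 1, tolerance = 1e-12)
    q_oracle <- quat_from_rotmat(rotmat_zyx(ang[1], ang[2], ang[3]))
    expect_equal(abs(sum(q * q_oracle)), 1, tolerance = 1e-9)
  }
  expect_error(euler_to_quaternion(c(NA, 0, 0)), "finite")
})

test_that("quaternion sign canonicalisation fixes the double cover", {
  expect_equal(canonicalize_quaternion(c(1, 0, 0, 0)), c(1, 0, 0, 0))
  expect_equal(canonicalize_quaternion(c(-1, 0, 0, 0)), c(1, 0, 0, 0))
  expect_equal(canonicalize_quaternion(c(0, -1, 0, 0)), c(0, 1, 0, 0))
  expect_error(canonicalize_quaternion(c(0, 0, 0, 0)), "zero quaternion")
  set.seed(7)
  q <- random_unit_quats(50)
  expect_true(all(q[, 1] > 0 | (q[, 1] == 0 & q[, 2] >= 0)))
})

test_that("BVH files round-trip through write_bvh/read_bvh", {
  f <- tempfile(fileext = ".bvh")
  writeLines(minimal_bvh_text(), f)
  expect_warning(m <- read_bvh(f), "17")  # 2-joint fixture, warn not fail
  expect_equal(n_frames(m), 3L)
  expect_equal(m$frame_time, 0.00833333)
  expect_equal(m$euler[2, 1, ], c(0, 5, 20))          # x,y,z slots of root
  expect_equal(m$root_translation[3, ], c(0, 96, 0))

  f2 <- tempfile(fileext = ".bvh")
  suppressWarnings({
    write_bvh(m, f2)
    m2 <- read_bvh(f2)
  })
  expect_equal(m2$euler, m$euler, tolerance = 1e-6)
  expect_equal(m2$root_translation, m$root_translation, tolerance = 1e-6)

  # 17-joint synthetic motion round-trips within print precision
  motion <- smooth_motion(seed = 3, duration = 0.3)
  f3 <- tempfile(fileext = ".bvh")
  write_bvh(motion, f3)
  m3 <- read_bvh(f3)
  expect_equal(m3$euler, motion$euler, tolerance = 1e-5)
  expect_equal(m3$skeleton$joint_names, motion$skeleton$joint_names)
})

test_that("malformed BVH input is rejected with a parse error", {
  txt <- minimal_bvh_text()
  f <- tempfile(fileext = ".bvh")
  writeLines(txt[seq_len(which(txt == "MOTION") - 1L)], f)
  expect_error(suppressWarnings(read_bvh(f)), "no MOTION")

  bad <- txt
  bad[5] <- "\tCHANNELS 6 Xposition Yposition"
  writeLines(bad, f)
  expect_error(read_bvh(f), "CHANNELS")

  writeLines(txt[-1], f)  # no HIERARCHY keyword
  expect_error(suppressWarnings(read_bvh(f)), "no HIERARCHY")
  expect_error(read_bvh(tempfile()), "does not exist")
})

test_that("writing an empty motion errors and unwritable paths are reported", {
  motion <- smooth_motion(seed = 1, duration = 0.1)
  expect_error(suppressWarnings(
    write_bvh(motion, file.path(tempdir(), "no_dir_x", "a.bvh"))),
    "cannot write")
  m0 <- motion
  m0$euler <- motion$euler[0, , , drop = FALSE]
  expect_error(write_bvh(m0, tempfile()))
})

test_that("forward kinematics matches the homogeneous-matrix oracle", {
  # zero rotations: positions are cumulative offsets down each chain
  sk <- skeleton_model(c("A", "B", "C"), c(NA, 1, 2),
                       rbind(c(0, 0, 0), c(1, 2, 3), c(4, 5, 6)))
  eu <- array(0, c(2, 3, 3))
  m <- motion_sequence(sk, eu, matrix(0, 2, 3), 1 / 120)
  pos <- forward_kinematics(m)
  expect_equal(pos[1, 3, ], c(5, 7, 9))

  # root rotated 90 degrees about z, child offset (1,0,0) -> (0,1,0)
  eu2 <- array(0, c(1, 3, 3)); eu2[1, 1, 3] <- 90
  m2 <- motion_sequence(sk, eu2, matrix(0, 1, 3), 1 / 120)
  p2 <- forward_kinematics(m2)
  expect_equal(p2[1, 2, ], c(-2, 1, 3), tolerance = 1e-12)

  # random rotations vs an explicit matrix-stack oracle
  set.seed(11)
  eu3 <- array(runif(5 * 3 * 3, -180, 180), c(5, 3, 3))
  tr3 <- matrix(runif(15, -10, 10), 5, 3)
  m3 <- motion_sequence(sk, eu3, tr3, 1 / 120)
  p3 <- forward_kinematics(m3)
  for (f in 1:5) {
    R1 <- rotmat_zyx(eu3[f, 1, 1] * pi / 180, eu3[f, 1, 2] * pi / 180,
                     eu3[f, 1, 3] * pi / 180)
    R2 <- rotmat_zyx(eu3[f, 2, 1] * pi / 180, eu3[f, 2, 2] * pi / 180,
                     eu3[f, 2, 3] * pi / 180)
    pB <- tr3[f, ] + drop(R1 %*% sk$offsets[2, ])
    pC <- pB + drop(R1 %*% R2 %*% sk$offsets[3, ])
    expect_equal(p3[f, 2, ], pB, tolerance = 1e-9)
    expect_equal(p3[f, 3, ], pC, tolerance = 1e-9)
  }
})

test_that("skeleton constructor enforces the joint-tree invariants", {
  expect_error(skeleton_model(c("A", "B"), c(NA, NA), matrix(0, 2, 3)),
               "exactly one root")
  expect_error(skeleton_model(c("A", "B", "C"), c(NA, 3, 2), matrix(0, 3, 3)),
               "topological")
  expect_silent(default_skeleton())
  expect_length(default_skeleton()$joint_names, 17L)
})
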