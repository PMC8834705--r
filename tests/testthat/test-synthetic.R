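test_that("generator configuration validates its invariants", {
  expect_error(generator_config(grade_mix = matrix(0.5, 8, 3)), "sum to 1")
  expect_error(generator_config(perturb_scales = list(
    good = c(5, 3, 0.1), pass = c(4, 8, 0.2), fail = c(10, 16, 0.3))),
    "strictly increase")
  expect_error(generator_config(perturb_scales = list(
    good = c(1, 3, 0.1), pass = c(4, 8, 0.2), fail = c(10, 16, 1.0))),
    "warp strength")
  cfg <- generator_config()
  expect_equal(cfg$n_students, 95L)
  expect_equal(nrow(cfg$duration_mean_sd), 8L)
  expect_equal(cfg$duration_mean_sd[8, ], c(mean = 2.94, sd = 1.01))
})

test_that("teacher templates are deterministic and class-separated", {
  cfg <- tiny_config(seed = 5)
  t1a <- make_teacher_template(1, cfg)
  t1b <- make_teacher_template(1, cfg)
  expect_identical(t1a$motion$euler, t1b$motion$euler)
  expect_true(is.na(t1a$grade))
  expect_equal(t1a$role, "teacher")
  t2 <- make_teacher_template(2, cfg)
  d <- motion_distance(motion_quaternions(t1a$motion),
                       motion_quaternions(t2$motion))
  expect_gt(d$overall, 0)
  expect_error(make_teacher_template(9, cfg), "out of range")
})

test_that("class durations follow the configured distribution", {
  cfg <- generator_config(seed = 2)
  set.seed(77)
  durs <- replicate(200, motionseq:::draw_duration(cfg, 8))
  se <- cfg$duration_mean_sd[8, 2] / sqrt(200)
  expect_lt(abs(mean(durs) - cfg$duration_mean_sd[8, 1]), 3 * se + 0.05)
})

test_that("students inherit the template up to grade-scaled perturbation", {
  cfg <- tiny_config(seed = 3, perturb_scales = list(
    good = c(0, 0, 0), pass = c(2, 4, 0.1), fail = c(6, 10, 0.25)))
  tm <- make_teacher_template(4, cfg)
  qt <- motion_quaternions(tm$motion)
  # zero perturbation: student is a time-resampled teacher, distance ~ 0
  st0 <- make_student_motion(tm, "good", cfg, subject = 2)
  d0 <- motion_distance(motion_quaternions(st0$motion), qt)$overall
  expect_lt(d0, 0.01)
  # degenerate duration spread: frame count = round(duration * frame_rate)
  cfg_fixed <- generator_config(seed = 3,
                                duration_mean_sd = cbind(rep(2.5, 8),
                                                         rep(0, 8)),
                                perturb_scales = list(good = c(0, 0, 0),
                                                      pass = c(2, 4, 0.1),
                                                      fail = c(6, 10, 0.25)))
  tm_f <- make_teacher_template(4, cfg_fixed)
  st_f <- make_student_motion(tm_f, "good", cfg_fixed, subject = 5)
  expect_equal(n_frames(st_f$motion), round(2.5 * cfg_fixed$frame_rate))
  expect_error(make_student_motion(st0, "pass", cfg), "teacher")
  expect_error(make_student_motion(tm, "excellent", cfg), "unknown grade")
})

test_that("perturbation magnitude orders the grade distance distributions", {
  cfg <- tiny_config(seed = 13)
  tm <- make_teacher_template(2, cfg)
  qt <- motion_quaternions(tm$motion)
  dist_of <- function(grade, subjects) vapply(subjects, function(s) {
    st <- make_student_motion(tm, grade, cfg, subject = s)
    motion_distance(motion_quaternions(st$motion), qt)$overall
  }, numeric(1))
  d_good <- dist_of("good", 1:18)
  d_pass <- dist_of("pass", 101:118)
  d_fail <- dist_of("fail", 201:218)
  expect_gt(mean(d_fail), mean(d_pass))
  expect_gt(mean(d_pass), mean(d_good))
  # distributional dominance, not only means
  expect_lt(stats::wilcox.test(d_good, d_fail,
                               alternative = "less")$p.value, 1e-4)
  expect_lt(stats::wilcox.test(d_pass, d_fail,
                               alternative = "less")$p.value, 0.01)
})

test_that("cohorts have the configured layout and reproduce bit-for-bit", {
  cfg <- tiny_config(seed = 8, n_students = 3)
  dir1 <- file.path(tempdir(), "cohort_a")
  dir2 <- file.path(tempdir(), "cohort_b")
  co <- generate_cohort(cfg, dir = dir1)
  expect_equal(nrow(co$labels), 8 * (3 + 3))
  expect_equal(sum(co$labels$role == "teacher"), 24)
  expect_true(all(is.na(co$labels$grade[co$labels$role == "teacher"])))
  expect_true(all(co$labels$grade[co$labels$role == "student"] %in%
                    c("good", "pass", "fail")))
  generate_cohort(cfg, dir = dir2)
  expect_identical(readLines(file.path(dir1, "labels.tsv")),
                   readLines(file.path(dir2, "labels.tsv")))
  f <- file.path(dir1, co$labels$file[1])
  expect_identical(readLines(f), readLines(file.path(dir2, co$labels$file[1])))
  # generated BVH parses back into a valid motion
  m <- read_bvh(f)
  expect_s3_class(m, "motion_sequence")
  expect_true(all(is.finite(m$euler)))

  cfg_pass <- tiny_config(seed = 8, n_students = 3,
                          grade_mix = matrix(rep(c(0, 1, 0), each = 8), 8, 3))
  co2 <- generate_cohort(cfg_pass)
  expect_true(all(co2$labels$grade[co2$labels$role == "student"] == "pass"))
})

test_that("unperturbed students are perfectly recognised by nearest template", {
  cfg <- tiny_config(seed = 21, n_students = 2, perturb_scales = list(
    good = c(0, 0, 0), pass = c(1, 2, 0.05), fail = c(3, 5, 0.1)))
  lib <- lapply(1:8, function(cl)
    motion_quaternions(make_teacher_template(cl, cfg)$motion))
  hits <- vapply(1:8, function(cl) {
    tm <- make_teacher_template(cl, cfg)
    st <- make_student_motion(tm, "good", cfg, subject = 1)
    f <- build_recognition_features(motion_quaternions(st$motion), lib)
    which.min(f) == cl
  }, logical(1))
  expect_true(all(hits))
})
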