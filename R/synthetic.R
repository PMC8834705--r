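# Synthetic motion-cohort generator: eight motion classes, each defined by
# smooth class-specific joint-angle curves; a teacher performs three
# repetitions per class and students perform graded (good/pass/fail)
# perturbed versions.  Grades are defined by the perturbation scale that
# generated them, so downstream parameter-recovery has exact ground truth.

# study-scale class durations, mean +/- sd seconds per class
default_durations <- function() {
  cbind(mean = c(12.13, 21.72, 16.58, 15.09, 19.43, 16.40, 13.17, 2.94),
        sd   = c(2.80, 4.01, 3.78, 3.94, 4.67, 3.86, 3.50, 1.01))
}

# per-class grade proportions (good, pass, fail) out of 95 students
default_grade_mix <- function() {
  counts <- rbind(c(16, 57, 22), c(21, 53, 21), c(26, 58, 11), c(22, 58, 15),
                  c(20, 57, 18), c(23, 55, 17), c(29, 59, 7), c(61, 34, 0))
  counts / rowSums(counts)
}

#' Synthetic cohort generator configuration
#'
#' Defaults emulate the study conditions: 8 motion classes with study-scale
#' durations, 3 teacher repetitions plus 95 students per class (98 motions,
#' 784 in all), and per-class good/pass/fail proportions matching the
#' reference grade table.  Grade severity is tied to perturbation magnitude:
#' each grade applies amplitude noise (deg RMS), constant joint offsets (deg)
#' and a monotone time warp, all strictly increasing from good to fail.
#'
#' @param seed integer master seed; per-motion substreams derive from
#'   (seed, class, subject).
#' @param frame_rate capture rate in Hz (default 120, the nominal inertial
#'   sensor family rate).
#' @param duration_mean_sd 8 x 2 matrix of per-class duration mean/sd in
#'   seconds.
#' @param n_students students per class (default 95).
#' @param grade_mix 8 x 3 matrix of per-class (good, pass, fail) proportions,
#'   each row summing to 1.
#' @param perturb_scales named list with elements `good`, `pass`, `fail`,
#'   each `c(amplitude_sd_deg, offset_deg, warp_strength)`; magnitudes must
#'   strictly increase from good to fail, warp strength in [0, 1).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, frame_rate = 120,
                             duration_mean_sd = default_durations(),
                             n_students = 95L,
                             grade_mix = default_grade_mix(),
                             perturb_scales = list(
                               good = c(1.5, 3, 0.05),
                               pass = c(4, 8, 0.15),
                               fail = c(10, 16, 0.30))) {
  duration_mean_sd <- as.matrix(duration_mean_sd)
  grade_mix <- as.matrix(grade_mix)
  if (ncol(duration_mean_sd) != 2L) stop("duration_mean_sd must be classes x 2")
  if (ncol(grade_mix) != 3L || nrow(grade_mix) != nrow(duration_mean_sd))
    stop("grade_mix must be classes x 3 (good, pass, fail)")
  if (any(abs(rowSums(grade_mix) - 1) > 1e-8))
    stop("grade proportions must sum to 1 per class")
  ps <- perturb_scales
  if (!all(c("good", "pass", "fail") %in% names(ps)))
    stop("perturb_scales needs good, pass and fail entries")
  inc <- rbind(ps$good, ps$pass, ps$fail)
  if (any(diff(inc[, 1]) <= 0) || any(diff(inc[, 2]) <= 0) ||
      any(diff(inc[, 3]) <= 0))
    stop("perturbation magnitudes must strictly increase good -> pass -> fail")
  if (any(inc[, 3] < 0 | inc[, 3] >= 1)) stop("warp strength must be in [0, 1)")
  structure(list(seed = as.integer(seed), frame_rate = frame_rate,
                 duration_mean_sd = duration_mean_sd,
                 n_students = as.integer(n_students), grade_mix = grade_mix,
                 perturb_scales = ps, n_classes = nrow(duration_mean_sd)),
            class = "generator_config")
}

# deterministic 32-bit substream seed from (seed, class, subject);
# subject 0 is the class template, teachers are negative subjects
motion_substream <- function(seed, class_id, subject) {
  as.integer((abs(seed) * 1000003 + class_id * 10007 +
                (subject + 100) * 101) %% 2147483647)
}

# class-specific smooth curve parameters: for every joint channel a mean
# angle plus 1-3 sinusoids in normalised phase
class_curves <- function(seed, class_id, n_joints = 17L) {
  set.seed(motion_substream(seed, class_id, 0L))
  curves <- vector("list", n_joints)
  for (j in seq_len(n_joints)) {
    ch <- vector("list", 3L)
    for (a in 1:3) {
      ns <- sample(1:3, 1)
      ch[[a]] <- list(mu = runif(1, -25, 25),
                      amp = runif(ns, 8, 40) / seq_len(ns),
                      freq = sample(1:3, ns, replace = TRUE),
                      phase = runif(ns, 0, 2 * pi))
    }
    curves[[j]] <- ch
  }
  # gentle root sway (cm) around standing height
  trans <- list(base = c(0, 95, 0),
                amp = runif(3, 1, 4), freq = sample(1:2, 3, replace = TRUE),
                phase = runif(3, 0, 2 * pi))
  list(joints = curves, trans = trans)
}

eval_curve <- function(cv, tau) {
  out <- rep(cv$mu, length(tau))
  for (s in seq_along(cv$amp))
    out <- out + cv$amp[s] * sin(2 * pi * cv$freq[s] * tau + cv$phase[s])
  out
}

# realise a motion from curves at a given duration; optional warp function
# and additive per-channel disturbance list
realize_motion <- function(curves, duration, frame_rate, skeleton,
                           warp = identity, disturb = NULL) {
  nf <- max(2L, as.integer(round(duration * frame_rate)))
  tau <- warp(seq(0, 1, length.out = nf))
  nj <- length(curves$joints)
  euler <- array(0, dim = c(nf, nj, 3))
  for (j in seq_len(nj))
    for (a in 1:3) {
      v <- eval_curve(curves$joints[[j]][[a]], tau)
      if (!is.null(disturb)) v <- v + disturb(j, a, tau)
      euler[, j, a] <- v
    }
  tr <- sapply(1:3, function(a)
    curves$trans$base[a] + curves$trans$amp[a] *
      sin(2 * pi * curves$trans$freq[a] * tau + curves$trans$phase[a]))
  motion_sequence(skeleton, euler, tr, 1 / frame_rate)
}

draw_duration <- function(config, class_id) {
  m <- config$duration_mean_sd[class_id, 1]
  s <- config$duration_mean_sd[class_id, 2]
  max(m / 4, rnorm(1, m, s))
}

#' Generate a teacher template motion for a class
#'
#' Deterministic per `(seed, class_id)`: every joint channel follows smooth
#' class-specific curves (sums of 1-3 seeded sinusoids), realised at the
#' class mean duration.
#'
#' @param class_id motion class in `1..n_classes`.
#' @param config a [generator_config()].
#' @return A `labelled_motion` list: `motion`, `class_id`, `grade` (NA),
#'   `role = "teacher"`, `subject_id`, plus the generating curves.
#' @export
make_teacher_template <- function(class_id, config = generator_config()) {
  if (class_id < 1L || class_id > config$n_classes)
    stop("class_id out of range 1..", config$n_classes)
  curves <- class_curves(config$seed, class_id)
  motion <- realize_motion(curves, config$duration_mean_sd[class_id, 1],
                           config$frame_rate, default_skeleton())
  structure(list(motion = motion, class_id = as.integer(class_id),
                 grade = NA_character_, role = "teacher",
                 subject_id = sprintf("teacher_c%d", class_id),
                 curves = curves),
            class = "labelled_motion")
}

# a teacher repetition: template curves, re-drawn duration, no perturbation
teacher_repetition <- function(template, rep_id, config) {
  set.seed(motion_substream(config$seed, template$class_id, -rep_id))
  dur <- draw_duration(config, template$class_id)
  motion <- realize_motion(template$curves, dur, config$frame_rate,
                           default_skeleton())
  structure(list(motion = motion, class_id = template$class_id,
                 grade = NA_character_, role = "teacher",
                 subject_id = sprintf("teacher_c%d_r%d", template$class_id,
                                      rep_id),
                 curves = template$curves),
            class = "labelled_motion")
}

#' Generate a graded student motion from a teacher template
#'
#' Applies, with grade-indexed magnitudes: a smooth strictly increasing time
#' re-parameterisation of `[0, 1]`; smooth per-channel amplitude noise with
#' the configured RMS (degrees); and constant angle offsets on a random joint
#' subset.  The duration is re-drawn from the class distribution.
#'
#' @param template a teacher `labelled_motion` (from
#'   [make_teacher_template()]).
#' @param grade `"good"`, `"pass"` or `"fail"`.
#' @param config a [generator_config()].
#' @param subject integer subject index used to derive the random substream.
#' @return A student `labelled_motion`.
#' @export
make_student_motion <- function(template, grade, config = generator_config(),
                                subject = 1L) {
  if (!identical(template$role, "teacher"))
    stop("template must be a teacher motion")
  if (!grade %in% c("good", "pass", "fail"))
    stop("unknown grade '", grade, "'")
  sc <- config$perturb_scales[[grade]]
  set.seed(motion_substream(config$seed, template$class_id, subject))
  dur <- draw_duration(config, template$class_id)

  # strictly increasing warp of [0,1]: w(t) = t + s*a*sin(pi t)/pi, |a|<1
  a <- runif(1, -0.95, 0.95)
  s <- sc[3]
  warp <- function(tau) tau + s * a * sin(pi * tau) / pi

  # smooth amplitude noise: two sinusoids per channel with total RMS sc[1];
  # constant offsets of sc[2] degrees on a random subset of joints
  nj <- length(template$curves$joints)
  n_off <- sample(2:5, 1)
  off_joints <- sample(seq_len(nj), n_off)
  off <- matrix(0, nj, 3)
  off[off_joints, ] <- sc[2] * runif(n_off * 3, 0.5, 1) *
    sample(c(-1, 1), n_off * 3, replace = TRUE)
  namp <- matrix(runif(nj * 3 * 2), nj * 3, 2)
  namp <- namp / sqrt(rowSums(namp^2) / 2) * sc[1]  # per-sinusoid RMS split
  nfreq <- matrix(sample(2:6, nj * 3 * 2, replace = TRUE), nj * 3, 2)
  nphase <- matrix(runif(nj * 3 * 2, 0, 2 * pi), nj * 3, 2)
  disturb <- function(j, a_, tau) {
    r <- (j - 1L) * 3L + a_
    off[j, a_] +
      namp[r, 1] * sin(2 * pi * nfreq[r, 1] * tau + nphase[r, 1]) +
      namp[r, 2] * sin(2 * pi * nfreq[r, 2] * tau + nphase[r, 2])
  }

  motion <- realize_motion(template$curves, dur, config$frame_rate,
                           default_skeleton(), warp = warp,
                           disturb = disturb)
  structure(list(motion = motion, class_id = template$class_id,
                 grade = grade, role = "student",
                 subject_id = sprintf("student_c%d_s%d", template$class_id,
                                      subject),
                 curves = NULL),
            class = "labelled_motion")
}

# grade drawn for (class, subject), deterministic given the config seed
draw_grade <- function(config, class_id, subject) {
  set.seed(motion_substream(config$seed, class_id, subject) + 1L)
  sample(c("good", "pass", "fail"), 1, prob = config$grade_mix[class_id, ])
}

#' Generate a labelled synthetic motion cohort
#'
#' Three teacher repetitions plus `n_students` graded students per class,
#' fully reproducible from the config seed.  With `dir` set, each motion is
#' written as a BVH file and a tab-delimited label file `labels.tsv`
#' (columns subject_id, class_id, role, grade, file) is written alongside.
#'
#' @param config a [generator_config()].
#' @param dir optional output directory for BVH files and the label file.
#' @return A list with `motions` (list of `labelled_motion`), `labels`
#'   (data.frame), and `config`.
#' @export
generate_cohort <- function(config = generator_config(), dir = NULL) {
  motions <- list()
  rows <- list()
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (cl in seq_len(config$n_classes)) {
    template <- make_teacher_template(cl, config)
    for (r in 1:3) {
      lm <- teacher_repetition(template, r, config)
      motions[[length(motions) + 1L]] <- lm
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = lm$subject_id, class_id = cl,
                   role = "teacher", grade = NA_character_,
                   file = paste0(lm$subject_id, ".bvh"))
    }
    for (st in seq_len(config$n_students)) {
      grade <- draw_grade(config, cl, st)
      lm <- make_student_motion(template, grade, config, subject = st)
      motions[[length(motions) + 1L]] <- lm
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = lm$subject_id, class_id = cl,
                   role = "student", grade = grade,
                   file = paste0(lm$subject_id, ".bvh"))
    }
  }
  labels <- do.call(rbind, rows)
  if (!is.null(dir)) {
    for (i in seq_along(motions))
      write_bvh(motions[[i]]$motion, file.path(dir, labels$file[i]))
    utils::write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(motions = motions, labels = labels, config = config)
}
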