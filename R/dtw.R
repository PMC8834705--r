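#' DTW configuration
#'
#' @param window_fraction Sakoe-Chiba band half-width as a fraction of the
#'   longer sequence (default 0.10, i.e. the warping window is limited to 10%
#'   of the window range).  The band is centred on the slope-corrected
#'   diagonal so unequal-length sequences stay alignable.
#' @param local_metric `"euclidean"` (default): Euclidean distance between
#'   canonicalised `[w,x,y,z]` vectors; `"geodesic"`: rotation angle between
#'   the quaternions.
#' @return A list of class `dtw_config`.
#' @export
dtw_config <- function(window_fraction = 0.10,
                       local_metric = c("euclidean", "geodesic")) {
  if (!is.numeric(window_fraction) || length(window_fraction) != 1L ||
      window_fraction <= 0 || window_fraction > 1)
    stop("window_fraction must be in (0, 1]")
  structure(list(window_fraction = window_fraction,
                 local_metric = match.arg(local_metric)),
            class = "dtw_config")
}

#' Banded DTW between two single-joint trajectories
#'
#' Dynamic program over steps \{(1,0), (0,1), (1,1)\} with cells outside the
#' slope-corrected band `|i*m/n - j| > ceil(window_fraction * max(n, m))`
#' forbidden.  If the requested band cannot connect the corners it is widened
#' to the minimum feasible width with a warning.  Among minimum-cost paths the
#' shortest is reported.
#'
#' @param a,b numeric matrices (frames x components), e.g. one joint's
#'   canonicalised quaternion trajectory.
#' @param config a [dtw_config()].
#' @return A list with `cumulative_distance` and `path_length` (number of
#'   cells on the optimal path).
#' @export
dtw_joint <- function(a, b, config = dtw_config()) {
  a <- as.matrix(a); b <- as.matrix(b)
  res <- dtw_band_cpp(a, b, config$window_fraction,
                      config$local_metric == "geodesic")
  if (isTRUE(res$band_widened))
    warning("warping band too narrow to connect the corners; widened to the ",
            "minimum feasible width")
  list(cumulative_distance = res$cumulative_distance,
       path_length = res$path_length)
}

#' Path-normalised DTW distance between two single-joint trajectories
#'
#' The cumulative warping-path cost divided by the path length, so sequences
#' of different durations are comparable.
#'
#' @inheritParams dtw_joint
#' @return Nonnegative scalar distance.
#' @export
joint_distance <- function(a, b, config = dtw_config()) {
  r <- dtw_joint(a, b, config)
  r$cumulative_distance / r$path_length
}

#' Per-joint DTW distance profile between two motions
#'
#' Runs banded DTW independently per joint (each joint may warp on its own
#' path) on the quaternion trajectories and averages the path-normalised
#' distances over the joints.
#'
#' @param student,teacher `quaternion_sequence` arrays (frames x joints x 4)
#'   with the same joint count.
#' @param config a [dtw_config()].
#' @return A list of class `distance_profile` with `per_joint` distances,
#'   `path_lengths`, and their mean `overall`.
#' @export
motion_distance <- function(student, teacher, config = dtw_config()) {
  sq <- unclass(student); tq <- unclass(teacher)
  if (dim(sq)[2] != dim(tq)[2])
    stop("motions have different joint counts")
  nj <- dim(sq)[2]
  res <- motion_dtw_cpp(flatten_quaternions(student),
                        flatten_quaternions(teacher),
                        nj, config$window_fraction,
                        config$local_metric == "geodesic")
  if (any(res$band_widened))
    warning("warping band too narrow to connect the corners; widened to the ",
            "minimum feasible width")
  per_joint <- res$cumulative_distance / res$path_length
  structure(list(per_joint = per_joint,
                 path_lengths = res$path_length,
                 overall = mean(per_joint)),
            class = "distance_profile")
}

#' Assessment feature vector: per-joint distances to a class's teacher
#'
#' For grading a motion against its own class, the feature vector is the
#' per-joint path-normalised DTW distance to the teacher, averaged over the
#' teacher's repetitions (one value per joint).  `mode = "scalar"` collapses
#' to the single overall mean distance.
#'
#' @param motion a `quaternion_sequence` for the candidate motion.
#' @param teacher_refs nonempty list of `quaternion_sequence` teacher
#'   repetitions of the same motion class.
#' @param config a [dtw_config()].
#' @param mode `"per_joint"` (default) or `"scalar"`.
#' @return Numeric feature vector (length = joints, or 1 for scalar mode).
#' @export
build_assessment_features <- function(motion, teacher_refs,
                                      config = dtw_config(),
                                      mode = c("per_joint", "scalar")) {
  mode <- match.arg(mode)
  if (!length(teacher_refs)) stop("teacher_refs must be nonempty")
  per <- vapply(teacher_refs,
                function(ref) motion_distance(motion, ref, config)$per_joint,
                numeric(dim(unclass(motion))[2]))
  feat <- rowMeans(matrix(per, nrow = dim(unclass(motion))[2]))
  if (mode == "scalar") mean(feat) else feat
}

#' Average several teacher repetitions into one reference sequence
#'
#' Repetitions are linearly resampled to the median repetition length per
#' joint component, averaged, re-normalised to unit quaternions, and
#' canonicalised.
#'
#' @param refs nonempty list of `quaternion_sequence` repetitions.
#' @return A `quaternion_sequence`.
#' @export
average_reference <- function(refs) {
  if (!length(refs)) stop("refs must be nonempty")
  lens <- vapply(refs, function(r) dim(unclass(r))[1], 1L)
  L <- as.integer(round(stats::median(lens)))
  nj <- dim(unclass(refs[[1]]))[2]
  acc <- array(0, dim = c(L, nj, 4))
  for (r in refs) {
    q <- unclass(r)
    tt <- seq(0, 1, length.out = dim(q)[1])
    to <- seq(0, 1, length.out = L)
    for (j in seq_len(nj))
      for (k in 1:4)
        acc[, j, k] <- acc[, j, k] + stats::approx(tt, q[, j, k], xout = to)$y
  }
  acc <- acc / length(refs)
  for (j in seq_len(nj)) {
    nrm <- sqrt(acc[, j, 1]^2 + acc[, j, 2]^2 + acc[, j, 3]^2 + acc[, j, 4]^2)
    for (k in 1:4) acc[, j, k] <- acc[, j, k] / nrm
    acc[, j, ] <- canonicalize_quaternion(matrix(acc[, j, ], ncol = 4))
  }
  structure(acc, class = "quaternion_sequence")
}

#' Recognition feature vector: distances to each class's reference
#'
#' One overall DTW distance per motion class, against that class's averaged
#' teacher reference; the class with the smallest component is the
#' nearest-template prediction.
#'
#' @param motion a `quaternion_sequence`.
#' @param teacher_library named list (one element per class) of either a
#'   single `quaternion_sequence` reference or a list of repetitions (which
#'   are averaged with [average_reference()]).
#' @param config a [dtw_config()].
#' @return Numeric vector, one distance per class, named by class.
#' @export
build_recognition_features <- function(motion, teacher_library,
                                       config = dtw_config()) {
  if (!length(teacher_library)) stop("teacher_library must cover all classes")
  vapply(teacher_library, function(ref) {
    if (is.list(ref) && !inherits(ref, "quaternion_sequence"))
      ref <- average_reference(ref)
    motion_distance(motion, ref, config)$overall
  }, numeric(1))
}
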