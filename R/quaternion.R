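#' Convert Euler angles to a unit quaternion (z, y, x application order)
#'
#' Composes the three axis rotations in z, y, x order, i.e. the quaternion
#' product `q = qz(gamma) * qy(beta) * qx(alpha)`, where `alpha`, `beta`,
#' `gamma` are the rotation angles about the x, y and z axes.  Component
#' layout is `[w, x, y, z]` with `w` the scalar part.
#'
#' @param angles numeric vector `c(alpha, beta, gamma)` in radians, or an
#'   n x 3 matrix of such rows.
#' @return A length-4 quaternion `[w,x,y,z]`, or an n x 4 matrix.
#' @export
euler_to_quaternion <- function(angles) {
  vec <- is.null(dim(angles))
  m <- if (vec) matrix(angles, ncol = 3) else as.matrix(angles)
  if (ncol(m) != 3) stop("angles must have 3 components (alpha, beta, gamma)")
  if (!all(is.finite(m))) stop("angles must be finite")
  ca <- cos(m[, 1] / 2); sa <- sin(m[, 1] / 2)
  cb <- cos(m[, 2] / 2); sb <- sin(m[, 2] / 2)
  cg <- cos(m[, 3] / 2); sg <- sin(m[, 3] / 2)
  q <- cbind(w = cg * cb * ca + sg * sb * sa,
             x = cg * cb * sa - sg * sb * ca,
             y = cg * sb * ca + sg * cb * sa,
             z = sg * cb * ca - cg * sb * sa)
  if (vec) q[1, ] else q
}

#' Canonicalise a quaternion's sign
#'
#' `q` and `-q` encode the same rotation (double cover); before any
#' vector-space distance the sign is fixed so that `w > 0`, or, when `w == 0`,
#' so that the first nonzero component is positive.
#'
#' @param q length-4 quaternion `[w,x,y,z]` or an n x 4 matrix of them.
#' @return Quaternion(s) with canonical sign.
#' @export
canonicalize_quaternion <- function(q) {
  vec <- is.null(dim(q))
  m <- if (vec) matrix(q, ncol = 4) else as.matrix(q)
  if (ncol(m) != 4) stop("quaternions must have 4 components")
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("cannot canonicalise a zero quaternion")
  # sign of the first nonzero component of each row
  s <- numeric(nrow(m))
  for (k in 1:4) {
    idx <- s == 0
    if (!any(idx)) break
    s[idx] <- sign(m[idx, k])
  }
  out <- m * s
  if (vec) out[1, ] else out
}

#' Quaternion trajectory of a motion
#'
#' Applies [euler_to_quaternion()] frame-by-frame and joint-by-joint (degrees
#' are converted to radians at this boundary) and canonicalises signs.  Root
#' translation is deliberately not part of the quaternion features.
#'
#' @param motion a [motion_sequence()].
#' @return A frames x joints x 4 array of class `quaternion_sequence`.
#' @export
motion_quaternions <- function(motion) {
  stopifnot(inherits(motion, "motion_sequence"))
  nf <- n_frames(motion)
  nj <- n_joints(motion$skeleton)
  out <- array(0, dim = c(nf, nj, 4))
  for (j in seq_len(nj)) {
    q <- euler_to_quaternion(motion$euler[, j, , drop = TRUE] * pi / 180)
    if (is.null(dim(q))) q <- matrix(q, ncol = 4)
    out[, j, ] <- canonicalize_quaternion(q)
  }
  structure(out, class = "quaternion_sequence")
}

#' Flatten a quaternion sequence to frames x (joints*4)
#'
#' Column blocks of four per joint, in joint order; the per-frame vectors used
#' by the vector-quantisation codebook and the recurrent models.
#'
#' @param quat a `quaternion_sequence` (frames x joints x 4 array).
#' @return A frames x (4*joints) numeric matrix.
#' @export
flatten_quaternions <- function(quat) {
  q <- unclass(quat)
  d <- dim(q)
  matrix(aperm(q, c(1, 3, 2)), nrow = d[1], ncol = d[2] * d[3])
}

# per-joint trajectory (frames x 4) from a quaternion sequence
joint_trajectory <- function(quat, j) {
  q <- unclass(quat)
  q[, j, , drop = TRUE]
}
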