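# Rotation-matrix elements for z,y,x-order Euler rotations, vectorised over
# frames.  Returns a frames x 9 matrix in row-major element order r11..r33.
rotation_elements <- function(deg) {
  a <- deg[, 1] * pi / 180; b <- deg[, 2] * pi / 180; g <- deg[, 3] * pi / 180
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  cbind(cg * cb, cg * sb * sa - sg * ca, cg * sb * ca + sg * sa,
        sg * cb, sg * sb * sa + cg * ca, sg * sb * ca - cg * sa,
        -sb,     cb * sa,                cb * ca)
}

# Frame-wise product of two stacks of 3x3 matrices stored as frames x 9 rows.
compose_rotations <- function(p, l) {
  cbind(p[,1]*l[,1] + p[,2]*l[,4] + p[,3]*l[,7],
        p[,1]*l[,2] + p[,2]*l[,5] + p[,3]*l[,8],
        p[,1]*l[,3] + p[,2]*l[,6] + p[,3]*l[,9],
        p[,4]*l[,1] + p[,5]*l[,4] + p[,6]*l[,7],
        p[,4]*l[,2] + p[,5]*l[,5] + p[,6]*l[,8],
        p[,4]*l[,3] + p[,5]*l[,6] + p[,6]*l[,9],
        p[,7]*l[,1] + p[,8]*l[,4] + p[,9]*l[,7],
        p[,7]*l[,2] + p[,8]*l[,5] + p[,9]*l[,8],
        p[,7]*l[,3] + p[,8]*l[,6] + p[,9]*l[,9])
}

#' Global joint positions by forward kinematics
#'
#' Walks the skeleton tree in topological order: each joint's global rotation
#' is the parent's global rotation composed with its local z,y,x Euler
#' rotation, and its global position is the parent position plus the
#' parent-rotated bone offset.  The root sits at its offset plus the root
#' translation.
#'
#' @param motion a [motion_sequence()].
#' @return A frames x joints x 3 array of class `position_sequence` (cm).
#' @export
forward_kinematics <- function(motion) {
  stopifnot(inherits(motion, "motion_sequence"))
  skel <- motion$skeleton
  nj <- n_joints(skel)
  nf <- n_frames(motion)
  parent <- skel$parent_index
  nonroot <- which(!is.na(parent))
  if (any(parent[nonroot] >= nonroot))
    stop("skeleton hierarchy is cyclic or not topologically ordered")

  rot_g <- vector("list", nj)
  pos <- array(0, dim = c(nf, nj, 3))
  for (j in seq_len(nj)) {
    loc <- rotation_elements(matrix(motion$euler[, j, ], nrow = nf))
    if (is.na(parent[j])) {
      rot_g[[j]] <- loc
      pos[, j, 1] <- skel$offsets[j, 1] + motion$root_translation[, 1]
      pos[, j, 2] <- skel$offsets[j, 2] + motion$root_translation[, 2]
      pos[, j, 3] <- skel$offsets[j, 3] + motion$root_translation[, 3]
    } else {
      p <- parent[j]
      rp <- rot_g[[p]]
      off <- skel$offsets[j, ]
      pos[, j, 1] <- pos[, p, 1] + rp[,1]*off[1] + rp[,2]*off[2] + rp[,3]*off[3]
      pos[, j, 2] <- pos[, p, 2] + rp[,4]*off[1] + rp[,5]*off[2] + rp[,6]*off[3]
      pos[, j, 3] <- pos[, p, 3] + rp[,7]*off[1] + rp[,8]*off[2] + rp[,9]*off[3]
      rot_g[[j]] <- compose_rotations(rp, loc)
    }
  }
  if (!all(is.finite(pos))) stop("forward kinematics produced non-finite positions")
  structure(pos, class = "position_sequence")
}

#' Flatten a position sequence to frames x (joints*3) pose vectors
#'
#' One row per frame; 51 columns for the 17-joint skeleton.  These are the
#' vectors clustered by the keyframe extractor.
#'
#' @param positions a `position_sequence` (frames x joints x 3 array).
#' @return A frames x (3*joints) numeric matrix.
#' @export
flatten_positions <- function(positions) {
  p <- unclass(positions)
  d <- dim(p)
  matrix(aperm(p, c(1, 3, 2)), nrow = d[1], ncol = d[2] * d[3])
}
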