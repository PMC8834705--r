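#' Construct a skeleton model
#'
#' A skeleton is an ordered joint tree: every non-root joint appears after its
#' parent, so kinematic passes can run in index order.  Offsets are the bone
#' vectors from the parent joint, in centimetres.
#'
#' @param joint_names character vector of joint identifiers.
#' @param parent_index integer vector, one entry per joint; `NA` for the root.
#' @param offsets numeric matrix, joints x 3, bone offset from the parent (cm).
#' @param channel_order list (one element per joint) of rotation channel names
#'   in file order, e.g. `c("Zrotation","Yrotation","Xrotation")`.  The root
#'   additionally carries three position channels when written to BVH.
#' @return An object of class `skeleton_model`.
#' @export
skeleton_model <- function(joint_names, parent_index, offsets,
                           channel_order = NULL) {
  joint_names <- as.character(joint_names)
  n <- length(joint_names)
  parent_index <- as.integer(parent_index)
  offsets <- as.matrix(offsets)
  storage.mode(offsets) <- "double"
  if (length(parent_index) != n)
    stop("parent_index must have one entry per joint")
  if (!all(dim(offsets) == c(n, 3)))
    stop("offsets must be a joints x 3 matrix")
  roots <- which(is.na(parent_index))
  if (length(roots) != 1L)
    stop("skeleton must have exactly one root joint")
  nonroot <- setdiff(seq_len(n), roots)
  if (any(parent_index[nonroot] >= nonroot) || any(parent_index[nonroot] < 1L))
    stop("joints must be listed in topological order (parent before child)")
  if (is.null(channel_order))
    channel_order <- rep(list(c("Zrotation", "Yrotation", "Xrotation")), n)
  if (length(channel_order) != n)
    stop("channel_order must have one entry per joint")
  structure(list(joint_names = joint_names,
                 parent_index = parent_index,
                 offsets = offsets,
                 channel_order = channel_order),
            class = "skeleton_model")
}

#' @export
print.skeleton_model <- function(x, ...) {
  cat("<skeleton_model> ", length(x$joint_names), " joints, root = ",
      x$joint_names[which(is.na(x$parent_index))], "\n", sep = "")
  invisible(x)
}

n_joints <- function(skeleton) length(skeleton$joint_names)

#' Default 17-joint humanoid skeleton
#'
#' A fixed 17-joint tree (hips, spine, chest, neck, head; upper arm, forearm
#' and hand on each side hanging from the chest; thigh, shin and foot on each
#' side hanging from the hips) with approximate adult segment lengths in
#' centimetres.  This is the skeleton used by the synthetic cohort generator.
#'
#' @return A `skeleton_model` with 17 joints.
#' @export
default_skeleton <- function() {
  j <- c("Hips", "Spine", "Chest", "Neck", "Head",
         "LeftUpperArm", "LeftForearm", "LeftHand",
         "RightUpperArm", "RightForearm", "RightHand",
         "LeftThigh", "LeftShin", "LeftFoot",
         "RightThigh", "RightShin", "RightFoot")
  parent <- c(NA, 1, 2, 3, 4,
              3, 6, 7,
              3, 9, 10,
              1, 12, 13,
              1, 15, 16)
  offsets <- rbind(
    c(0, 0, 0),      # Hips (root)
    c(0, 12, 0),     # Spine
    c(0, 16, 0),     # Chest
    c(0, 14, 0),     # Neck
    c(0, 11, 0),     # Head
    c(18, 10, 0),    # LeftUpperArm (from chest)
    c(28, 0, 0),     # LeftForearm
    c(25, 0, 0),     # LeftHand
    c(-18, 10, 0),   # RightUpperArm
    c(-28, 0, 0),    # RightForearm
    c(-25, 0, 0),    # RightHand
    c(9, -4, 0),     # LeftThigh (from hips)
    c(0, -42, 0),    # LeftShin
    c(0, -40, 12),   # LeftFoot
    c(-9, -4, 0),    # RightThigh
    c(0, -42, 0),    # RightShin
    c(0, -40, 12))   # RightFoot
  skeleton_model(j, parent, offsets)
}

#' Construct a motion sequence
#'
#' The universal container of the pipeline: per-frame Euler rotations for
#' every joint (degrees, applied in z, y, x order) plus the root translation.
#'
#' @param skeleton a `skeleton_model`.
#' @param euler numeric array frames x joints x 3; slices along the last
#'   dimension are the rotation angles about the x, y and z axes, in degrees.
#' @param root_translation numeric matrix frames x 3 (cm).
#' @param frame_time seconds per frame.
#' @return An object of class `motion_sequence`.
#' @export
motion_sequence <- function(skeleton, euler, root_translation, frame_time) {
  stopifnot(inherits(skeleton, "skeleton_model"))
  euler <- unclass(euler)
  if (length(dim(euler)) != 3L)
    stop("euler must be a frames x joints x 3 array")
  nf <- dim(euler)[1]
  if (nf < 1L) stop("motion must have at least one frame")
  if (dim(euler)[2] != n_joints(skeleton) || dim(euler)[3] != 3L)
    stop("euler dimensions do not match the skeleton")
  root_translation <- as.matrix(root_translation)
  if (!all(dim(root_translation) == c(nf, 3)))
    stop("root_translation must be frames x 3")
  if (!is.numeric(frame_time) || length(frame_time) != 1L || frame_time <= 0)
    stop("frame_time must be a positive scalar")
  if (!all(is.finite(euler)) || !all(is.finite(root_translation)))
    stop("motion contains non-finite values")
  structure(list(skeleton = skeleton, euler = euler,
                 root_translation = root_translation,
                 frame_time = frame_time),
            class = "motion_sequence")
}

#' @export
print.motion_sequence <- function(x, ...) {
  cat("<motion_sequence> ", n_frames(x), " frames x ",
      n_joints(x$skeleton), " joints, frame_time = ", x$frame_time,
      " s\n", sep = "")
  invisible(x)
}

#' Number of frames in a motion
#' @param motion a `motion_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(motion) dim(motion$euler)[1]
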