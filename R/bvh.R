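#' Read a BVH motion-capture file
#'
#' Parses the HIERARCHY section into a [skeleton_model()] and the MOTION
#' section into per-frame Euler angles and root translation.  Rotation
#' channels may appear in any per-joint order; the angles are stored by axis
#' and are always *applied* in z, y, x order downstream (see
#' [euler_to_quaternion()]).  `End Site` blocks are consumed but not treated
#' as joints.
#'
#' @param path path to a BVH file.
#' @return A [motion_sequence()].
#' @export
read_bvh <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "\\s+")
  nonempty <- which(vapply(toks, length, 1L) > 0L)
  if (!length(nonempty)) stop("parse error: empty file")

  first <- function(i) toks[[i]][1]
  hier <- which(vapply(nonempty, function(i) identical(first(i), "HIERARCHY"),
                       TRUE))
  if (!length(hier)) stop("parse error: no HIERARCHY section")
  motion_at <- NULL
  for (i in nonempty) if (identical(first(i), "MOTION")) { motion_at <- i; break }
  if (is.null(motion_at)) stop("parse error: no MOTION section")

  # --- hierarchy: recursive descent over the token stream -------------------
  idx_lines <- nonempty[nonempty < motion_at]
  stream <- list(lines = idx_lines, pos = 1L)
  peek <- function(s) if (s$pos <= length(s$lines)) toks[[s$lines[s$pos]]] else NULL
  lineno <- function(s) s$lines[min(s$pos, length(s$lines))]

  joints <- list()   # each: name, parent, offset, channels
  channel_cols <- list()  # per joint: channel names in file order
  env <- environment()

  parse_joint <- function(parent) {
    tk <- peek(stream)
    kind <- tk[1]
    if (!kind %in% c("ROOT", "JOINT"))
      stop("parse error at line ", lineno(stream), ": expected ROOT/JOINT")
    name <- tk[2]
    if (is.na(name)) stop("parse error at line ", lineno(stream),
                          ": joint without a name")
    stream$pos <<- stream$pos + 1L
    tk <- peek(stream)
    if (!identical(tk[1], "{"))
      stop("parse error at line ", lineno(stream), ": expected '{'")
    stream$pos <<- stream$pos + 1L

    tk <- peek(stream)
    if (!identical(tk[1], "OFFSET") || length(tk) < 4)
      stop("parse error at line ", lineno(stream), ": expected OFFSET x y z")
    off <- suppressWarnings(as.numeric(tk[2:4]))
    if (any(is.na(off)))
      stop("parse error at line ", lineno(stream), ": non-numeric OFFSET")
    stream$pos <<- stream$pos + 1L

    tk <- peek(stream)
    if (!identical(tk[1], "CHANNELS"))
      stop("parse error at line ", lineno(stream), ": expected CHANNELS")
    nch <- suppressWarnings(as.integer(tk[2]))
    chans <- tk[-(1:2)]
    if (is.na(nch) || length(chans) != nch)
      stop("parse error at line ", lineno(stream),
           ": CHANNELS count does not match channel list")
    stream$pos <<- stream$pos + 1L

    env$joints[[length(env$joints) + 1L]] <-
      list(name = name, parent = parent, offset = off, channels = chans)
    this_id <- length(env$joints)

    repeat {
      tk <- peek(stream)
      if (is.null(tk))
        stop("parse error: unterminated joint block for ", name)
      if (identical(tk[1], "}")) { stream$pos <<- stream$pos + 1L; break }
      if (tk[1] %in% c("JOINT")) {
        parse_joint(this_id)
      } else if (identical(tk[1], "End")) {
        # End Site { OFFSET ... }
        stream$pos <<- stream$pos + 1L
        if (!identical(peek(stream)[1], "{"))
          stop("parse error at line ", lineno(stream), ": expected '{' after End Site")
        stream$pos <<- stream$pos + 1L
        if (!identical(peek(stream)[1], "OFFSET"))
          stop("parse error at line ", lineno(stream), ": expected OFFSET in End Site")
        stream$pos <<- stream$pos + 1L
        if (!identical(peek(stream)[1], "}"))
          stop("parse error at line ", lineno(stream), ": unterminated End Site")
        stream$pos <<- stream$pos + 1L
      } else {
        stop("parse error at line ", lineno(stream), ": unexpected token '",
             tk[1], "'")
      }
    }
    invisible(this_id)
  }

  # skip the HIERARCHY keyword line
  if (identical(peek(stream)[1], "HIERARCHY")) stream$pos <- stream$pos + 1L
  parse_joint(NA_integer_)

  nj <- length(joints)
  if (nj != 17L)
    warning("skeleton has ", nj, " joints (pipeline reference skeleton has 17)")

  # --- motion section -------------------------------------------------------
  after <- nonempty[nonempty > motion_at]
  if (length(after) < 2L) stop("parse error: truncated MOTION section")
  tk <- toks[[after[1]]]
  if (!identical(tk[1], "Frames:"))
    stop("parse error at line ", after[1], ": expected 'Frames:'")
  nf <- suppressWarnings(as.integer(tk[2]))
  if (is.na(nf) || nf < 1L)
    stop("parse error at line ", after[1], ": bad frame count")
  tk <- toks[[after[2]]]
  if (!(identical(tk[1], "Frame") && identical(tk[2], "Time:")))
    stop("parse error at line ", after[2], ": expected 'Frame Time:'")
  frame_time <- suppressWarnings(as.numeric(tk[3]))
  if (is.na(frame_time) || frame_time <= 0)
    stop("parse error at line ", after[2], ": bad frame time")

  data_lines <- after[-(1:2)]
  if (length(data_lines) < nf)
    stop("parse error: header declares ", nf, " frames but only ",
         length(data_lines), " data rows present")
  data_lines <- data_lines[seq_len(nf)]
  total_ch <- sum(vapply(joints, function(j) length(j$channels), 1L))
  vals <- vapply(data_lines, function(i) {
    v <- suppressWarnings(as.numeric(toks[[i]]))
    if (length(v) != total_ch || any(is.na(v)))
      stop("parse error at line ", i, ": expected ", total_ch,
           " numeric channel values")
    v
  }, numeric(total_ch))
  vals <- t(vals)  # frames x channels

  skel <- skeleton_model(
    joint_names = vapply(joints, `[[`, "", "name"),
    parent_index = vapply(joints, function(j) as.integer(j$parent), 1L),
    offsets = do.call(rbind, lapply(joints, `[[`, "offset")),
    channel_order = lapply(joints, function(j)
      j$channels[grepl("rotation$", j$channels)]))

  euler <- array(0, dim = c(nf, nj, 3))
  root_translation <- matrix(0, nf, 3)
  col <- 0L
  axis_of <- c(Xrotation = 1L, Yrotation = 2L, Zrotation = 3L,
               Xposition = 1L, Yposition = 2L, Zposition = 3L)
  for (j in seq_len(nj)) {
    for (ch in joints[[j]]$channels) {
      col <- col + 1L
      if (!ch %in% names(axis_of))
        stop("parse error: unknown channel type '", ch, "'")
      if (grepl("position$", ch)) {
        if (j == 1L) root_translation[, axis_of[[ch]]] <- vals[, col]
        # non-root position channels are read but dropped
      } else {
        euler[, j, axis_of[[ch]]] <- vals[, col]
      }
    }
  }
  motion_sequence(skel, euler, root_translation, frame_time)
}

#' Write a motion sequence to a BVH file
#'
#' Inverse of [read_bvh()] up to numeric print precision (six decimals).
#' Rotation channels are written in each joint's recorded channel order; the
#' root gains three position channels for the translation.
#'
#' @param motion a [motion_sequence()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bvh <- function(motion, path) {
  stopifnot(inherits(motion, "motion_sequence"))
  if (n_frames(motion) < 1L) stop("motion has no frames")
  skel <- motion$skeleton
  nj <- n_joints(skel)
  children <- lapply(seq_len(nj), function(j) which(skel$parent_index == j))
  fmt <- function(x) sprintf("%.6f", x)

  out <- c("HIERARCHY")
  emit_joint <- function(j, depth) {
    ind <- strrep("\t", depth)
    kw <- if (is.na(skel$parent_index[j])) "ROOT" else "JOINT"
    out <<- c(out, paste0(ind, kw, " ", skel$joint_names[j]), paste0(ind, "{"))
    ind2 <- strrep("\t", depth + 1L)
    out <<- c(out, paste0(ind2, "OFFSET ",
                          paste(fmt(skel$offsets[j, ]), collapse = " ")))
    rot <- skel$channel_order[[j]]
    chans <- if (is.na(skel$parent_index[j]))
      c("Xposition", "Yposition", "Zposition", rot) else rot
    out <<- c(out, paste0(ind2, "CHANNELS ", length(chans), " ",
                          paste(chans, collapse = " ")))
    if (length(children[[j]])) {
      for (c_ in children[[j]]) emit_joint(c_, depth + 1L)
    } else {
      out <<- c(out, paste0(ind2, "End Site"), paste0(ind2, "{"),
                paste0(strrep("\t", depth + 2L), "OFFSET 0.000000 0.000000 0.000000"),
                paste0(ind2, "}"))
    }
    out <<- c(out, paste0(ind, "}"))
  }
  emit_joint(which(is.na(skel$parent_index)), 0L)

  nf <- n_frames(motion)
  axis_of <- c(Xrotation = 1L, Yrotation = 2L, Zrotation = 3L)
  cols <- list(motion$root_translation[, 1, drop = FALSE],
               motion$root_translation[, 2, drop = FALSE],
               motion$root_translation[, 3, drop = FALSE])
  for (j in seq_len(nj))
    for (ch in skel$channel_order[[j]])
      cols[[length(cols) + 1L]] <- motion$euler[, j, axis_of[[ch]], drop = FALSE]
  mat <- do.call(cbind, cols)
  rows <- apply(matrix(sprintf("%.6f", mat), nrow = nf), 1, paste,
                collapse = " ")
  out <- c(out, "MOTION", paste0("Frames: ", nf),
           paste0("Frame Time: ", sprintf("%.8f", motion$frame_time)), rows)
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) stop("cannot write BVH file: ",
                                          conditionMessage(e)))
  invisible(path)
}
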