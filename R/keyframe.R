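#' Keyframe compression configuration
#'
#' @param c_rate compression rate in (0, 1]: the fraction of original frames
#'   kept as keyframes.  15% is the pipeline default, the rate at which
#'   reconstruction error has flattened out on the study-scale motions.
#' @param kmeans_max_iter Lloyd iteration cap per restart.
#' @param kmeans_restarts number of seeded k-means restarts; the best
#'   within-cluster sum of squares wins.  The initialisation spreads centroids
#'   over the temporal extent, which for smooth motions is already close to
#'   the optimum, so the default keeps a single restart.
#' @param seed integer seed controlling the restarts.
#' @return A list of class `compression_config`.
#' @export
compression_config <- function(c_rate = 0.15, kmeans_max_iter = 30,
                               kmeans_restarts = 1, seed = 1L) {
  if (!is.numeric(c_rate) || length(c_rate) != 1L || c_rate <= 0 || c_rate > 1)
    stop("c_rate must be in (0, 1]")
  structure(list(c_rate = c_rate,
                 kmeans_max_iter = as.integer(kmeans_max_iter),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 seed = as.integer(seed)),
            class = "compression_config")
}

#' Number of keyframes at a compression rate
#'
#' `k = c_rate * n_frames`, rounded half-up and clamped to `[1, n_frames]`.
#'
#' @param c_rate compression rate in (0, 1].
#' @param n_frames original frame count.
#' @return Integer keyframe count.
#' @export
compute_k <- function(c_rate, n_frames) {
  if (!is.numeric(c_rate) || length(c_rate) != 1L || c_rate <= 0 || c_rate > 1)
    stop("c_rate must be in (0, 1]")
  if (n_frames < 1L) stop("n_frames must be >= 1")
  k <- floor(c_rate * n_frames + 0.5)
  as.integer(min(max(k, 1), n_frames))
}

#' Extract keyframes by k-means clustering of pose vectors
#'
#' Clusters the per-frame flattened joint coordinates (51 dimensions for the
#' 17-joint skeleton, Euclidean distance) into `k` groups and takes, for each
#' centroid, the original frame closest to it.  Centroid-to-frame collisions
#' are backfilled with the next-nearest unused frame so exactly `k` distinct
#' frames result; the first and last frames are force-included (replacing the
#' worst-ranked keyframes) so every non-keyframe has flanking keyframes for
#' interpolation.
#'
#' @param positions a `position_sequence` from [forward_kinematics()].
#' @param config a [compression_config()].
#' @return A list of class `keyframe_result` with elements `k`, `indices`
#'   (sorted frame indices), `key_positions`, and `reconstruction_error` (cm).
#' @export
extract_keyframes <- function(positions, config = compression_config()) {
  stopifnot(inherits(config, "compression_config"))
  x <- flatten_positions(positions)
  nf <- nrow(x)
  k <- compute_k(config$c_rate, nf)
  if (k > nf) stop("more keyframes requested than frames available")
  if (nf >= 2L) k <- max(k, 2L)  # both endpoints are always keyframes

  if (k == nf) {
    idx <- seq_len(nf)
  } else {
    n_distinct <- nrow(unique(round(x, 9)))
    if (n_distinct < k) {
      # degenerate input (e.g. constant motion): fall back to even temporal
      # spacing, which preserves determinism and endpoint coverage
      idx <- unique(round(seq(1, nf, length.out = k)))
      while (length(idx) < k)
        idx <- sort(union(idx, setdiff(seq_len(nf), idx)[1]))
    } else {
      best <- NULL
      for (r in seq_len(max(1L, config$kmeans_restarts))) {
        set.seed(config$seed + r - 1L)
        # one frame sampled from each of k temporal strata
        bins <- split(seq_len(nf), cut(seq_len(nf), k, labels = FALSE))
        init_idx <- vapply(bins, function(b) b[sample.int(length(b), 1L)], 1L)
        init <- x[init_idx, , drop = FALSE]
        dup <- duplicated(round(init, 9))
        if (any(dup)) {
          pool <- setdiff(which(!duplicated(round(x, 9))), init_idx)
          init_idx[dup] <- pool[seq_len(sum(dup))]
          init <- x[sort(init_idx), , drop = FALSE]
        }
        km <- suppressWarnings(
          kmeans(x, centers = init, iter.max = config$kmeans_max_iter,
                 algorithm = "Lloyd"))
        if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
      }
      idx <- nearest_frames(x, best$centers)
      idx <- force_endpoints(idx$indices, idx$dist_to_centroid, nf)
    }
  }
  idx <- sort(unique(idx))
  kp <- unclass(positions)[idx, , , drop = FALSE]
  res <- structure(list(k = length(idx), indices = idx,
                        key_positions = kp, reconstruction_error = NA_real_),
                   class = "keyframe_result")
  res$reconstruction_error <- reconstruction_error(positions, res)
  res
}

# Map each centroid to its nearest original frame; collisions backfilled with
# the next-nearest unused frame so the number of distinct indices equals k.
nearest_frames <- function(x, centers) {
  nf <- nrow(x); k <- nrow(centers)
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  # squared distances frame x centroid via the expansion trick
  d2 <- outer(xx, cc, "+") - 2 * x %*% t(centers)
  d2[d2 < 0] <- 0
  used <- logical(nf)
  indices <- integer(k)
  dist_to_centroid <- numeric(k)
  ord <- order(apply(d2, 2, min))  # assign best-matched centroids first
  for (ci in ord) {
    pref <- order(d2[, ci])
    pick <- pref[!used[pref]][1]
    used[pick] <- TRUE
    indices[ci] <- pick
    dist_to_centroid[ci] <- sqrt(d2[pick, ci])
  }
  list(indices = indices, dist_to_centroid = dist_to_centroid)
}

# Force frames 1 and nf into the index set, replacing the worst-ranked
# (least centroid-representative) keyframes.
force_endpoints <- function(indices, rank_dist, nf) {
  for (endpoint in c(1L, nf)) {
    if (!endpoint %in% indices) {
      replaceable <- which(!indices %in% c(1L, nf))
      worst <- replaceable[which.max(rank_dist[replaceable])]
      indices[worst] <- endpoint
      rank_dist[worst] <- -Inf
    }
  }
  indices
}

#' Linear interpolation between two keyframe poses
#'
#' `u(t) = (t2 - t) / (t2 - t1)`; the interpolated pose is
#' `u(t) * p1 + (1 - u(t)) * p2`, applied per joint coordinate.
#'
#' @param p1,p2 poses (any conformable numeric arrays) at times `t1` and `t2`.
#' @param t1,t,t2 times with `t1 < t < t2` (frame indices in this pipeline).
#' @return The interpolated pose.
#' @export
interpolate_frame <- function(p1, p2, t1, t, t2) {
  if (!(t1 < t && t < t2)) stop("t must lie strictly between t1 and t2")
  u <- (t2 - t) / (t2 - t1)
  u * p1 + (1 - u) * p2
}

#' Reconstruction error of a keyframe set
#'
#' Rebuilds all frames (keyframes verbatim, non-keyframes linearly
#' interpolated between flanking keyframes with frame index as the time
#' variable) and averages the per-frame posture distance, i.e. the sum over
#' joints of the Euclidean displacement of each joint, over all frames.
#'
#' @param original a `position_sequence`.
#' @param keyframes a `keyframe_result` drawn from `original`.
#' @return Mean posture distance in centimetres.
#' @export
reconstruction_error <- function(original, keyframes) {
  p <- unclass(original)
  idx <- keyframes$indices
  if (!length(idx)) stop("empty keyframe set")
  nf <- dim(p)[1]
  if (idx[1] != 1L || idx[length(idx)] != nf)
    stop("keyframe set must include the first and last frame")
  recon <- p
  for (s in seq_len(length(idx) - 1L)) {
    a <- idx[s]; b <- idx[s + 1L]
    if (b - a > 1L) {
      for (t in (a + 1L):(b - 1L))
        recon[t, , ] <- interpolate_frame(p[a, , ], p[b, , ], a, t, b)
    }
  }
  d2 <- (p - recon)^2
  disp <- sqrt(d2[, , 1] + d2[, , 2] + d2[, , 3])  # frames x joints
  if (is.null(dim(disp))) disp <- matrix(disp, nrow = nf)
  mean(rowSums(disp))
}

#' Reconstruction error across compression rates
#'
#' Runs [extract_keyframes()] at each rate and tabulates the error; used to
#' choose a working compression rate (error should flatten as the rate
#' rises).
#'
#' @param positions a `position_sequence`.
#' @param rates numeric vector of compression rates in (0, 1].
#' @param config a [compression_config()]; its `c_rate` is ignored.
#' @return A data.frame with columns `rate`, `k`, `error`.
#' @export
compression_sweep <- function(positions, rates,
                              config = compression_config()) {
  if (!length(rates))
    return(data.frame(rate = numeric(), k = integer(), error = numeric()))
  rows <- lapply(rates, function(r) {
    cfg <- config; cfg$c_rate <- r
    kf <- extract_keyframes(positions, cfg)
    data.frame(rate = r, k = kf$k, error = kf$reconstruction_error)
  })
  do.call(rbind, rows)
}
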