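# Independent oracles and small fixtures shared across the suite.

# rotation matrix for z,y,x-order Euler rotations (radians)
rotmat_zyx <- function(alpha, beta, gamma) {
  rx <- rbind(c(1, 0, 0), c(0, cos(alpha), -sin(alpha)),
              c(0, sin(alpha), cos(alpha)))
  ry <- rbind(c(cos(beta), 0, sin(beta)), c(0, 1, 0),
              c(-sin(beta), 0, cos(beta)))
  rz <- rbind(c(cos(gamma), -sin(gamma), 0), c(sin(gamma), cos(gamma), 0),
              c(0, 0, 1))
  rz %*% ry %*% rx
}

# Shepperd-style rotation-matrix -> quaternion conversion
quat_from_rotmat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, s / 4)
    }
  }
  q / sqrt(sum(q^2))
}

# Exhaustive monotone-path DTW oracle: enumerates every warping path over
# steps {(1,0),(0,1),(1,1)} and returns the minimal cumulative cost (and the
# shortest path length among minimal-cost paths).  Full window only.
brute_dtw <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a); m <- nrow(b)
  lc <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  best <- c(cost = Inf, len = Inf)
  rec <- function(i, j, cost, len) {
    cost <- cost + lc(i, j)
    len <- len + 1
    if (i == n && j == m) {
      if (cost < best["cost"] - 1e-15 ||
          (abs(cost - best["cost"]) <= 1e-15 && len < best["len"]))
        best <<- c(cost = cost, len = len)
      return(invisible())
    }
    if (i < n) rec(i + 1, j, cost, len)
    if (j < m) rec(i, j + 1, cost, len)
    if (i < n && j < m) rec(i + 1, j + 1, cost, len)
  }
  rec(1, 1, 0, 0)
  best
}

# HMM likelihood by explicit summation over all state paths
brute_hmm_loglik <- function(model, obs) {
  N <- model$N; T_ <- length(obs)
  paths <- do.call(expand.grid, rep(list(seq_len(N)), T_))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    st <- as.integer(paths[r, ])
    p <- model$pi[st[1]] * model$B[st[1], obs[1]]
    if (T_ > 1) for (t in 2:T_)
      p <- p * model$A[st[t - 1], st[t]] * model$B[st[t], obs[t]]
    tot <- tot + p
  }
  log(tot)
}

random_hmm <- function(N, M) {
  rd <- function(n) { g <- rgamma(n, 1); g / sum(g) }
  hmm_model(rd(N), t(sapply(seq_len(N), function(i) rd(N))),
            t(sapply(seq_len(N), function(i) rd(M))))
}

random_unit_quats <- function(n) {
  q <- matrix(rnorm(4 * n), n, 4)
  canonicalize_quaternion(q / sqrt(rowSums(q^2)))
}

# central finite-difference gradient of the RNN loss over flattened params
fd_rnn_gradient <- function(params, kind, seqs, y, K, eps = 1e-5) {
  flat <- unlist(params)
  vapply(seq_along(flat), function(i) {
    p1 <- utils::relist(replace(flat, i, flat[i] + eps), params)
    p2 <- utils::relist(replace(flat, i, flat[i] - eps), params)
    (motionseq:::rnn_loss_grad(p1, kind, seqs, y, K, want_grad = FALSE)$loss -
     motionseq:::rnn_loss_grad(p2, kind, seqs, y, K, want_grad = FALSE)$loss) /
      (2 * eps)
  }, numeric(1))
}

# small generator config for fast cohort tests: short motions, few students
tiny_config <- function(seed = 1L, n_students = 6L, ...) {
  generator_config(seed = seed, n_students = n_students,
                   duration_mean_sd = cbind(rep(2.5, 8), rep(0.4, 8)), ...)
}

# a smooth single-motion fixture
smooth_motion <- function(seed = 1L, duration = 3) {
  cfg <- generator_config(seed = seed,
                          duration_mean_sd = cbind(rep(duration, 8),
                                                   rep(0.1, 8)))
  make_teacher_template(1L, cfg)$motion
}

minimal_bvh_text <- function() {
  c("HIERARCHY",
    "ROOT Hips",
    "{",
    "\tOFFSET 0.0 0.0 0.0",
    "\tCHANNELS 6 Xposition Yposition Zposition Zrotation Yrotation Xrotation",
    "\tJOINT Spine",
    "\t{",
    "\t\tOFFSET 0.0 10.0 0.0",
    "\t\tCHANNELS 3 Zrotation Yrotation Xrotation",
    "\t\tEnd Site",
    "\t\t{",
    "\t\t\tOFFSET 0.0 5.0 0.0",
    "\t\t}",
    "\t}",
    "}",
    "MOTION",
    "Frames: 3",
    "Frame Time: 0.00833333",
    "0 95 0 10 0 0 5 0 0",
    "0 95 1 20 5 0 10 2 0",
    "0 96 0 30 10 5 15 4 1")
}
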