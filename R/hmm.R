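#' Fit a vector-quantisation codebook for discrete HMM emissions
#'
#' k-means (Euclidean) on the pooled per-frame flattened quaternion vectors
#' (68 dimensions for 17 joints); a frame's observation symbol is the index
#' of its nearest centroid.
#'
#' @param motions list of `quaternion_sequence` objects.
#' @param M codebook size (number of observation symbols), >= 2.
#' @param seed integer seed.
#' @return A list of class `vq_codebook` with the `M x 68` centroid matrix.
#' @export
fit_codebook <- function(motions, M = 16L, seed = 1L) {
  if (!length(motions)) stop("no motions supplied")
  frames <- do.call(rbind, lapply(motions, flatten_quaternions))
  M <- as.integer(M)
  if (M < 1L) stop("codebook needs at least one symbol")
  if (M > nrow(frames))
    stop("codebook size exceeds the number of training frames")
  n_distinct <- nrow(unique(round(frames, 9)))
  if (M > n_distinct) {
    warning("codebook size reduced to the ", n_distinct,
            " distinct pose(s) present")
    M <- n_distinct
  }
  if (M == 1L)
    return(structure(list(centroids = matrix(colMeans(frames), 1)),
                     class = "vq_codebook"))
  set.seed(seed)
  km <- suppressWarnings(kmeans(frames, centers = M, nstart = 3,
                                iter.max = 50))
  structure(list(centroids = km$centers), class = "vq_codebook")
}

#' Quantise a motion into a symbol sequence
#'
#' @param motion a `quaternion_sequence`.
#' @param codebook a `vq_codebook` from [fit_codebook()].
#' @return Integer vector of symbols in `1..M`, one per frame.
#' @export
quantize <- function(motion, codebook) {
  x <- flatten_quaternions(motion)
  cc <- codebook$centroids
  d2 <- outer(rowSums(x^2), rowSums(cc^2), "+") - 2 * x %*% t(cc)
  max.col(-d2, ties.method = "first")
}

#' Construct a discrete-emission hidden Markov model
#'
#' `lambda = [N, M, pi, A, B]`: `N` hidden states, `M` observation symbols,
#' initial distribution `pi`, transition matrix `A` (rows sum to 1) and
#' emission matrix `B` (rows sum to 1).
#'
#' @param pi initial state probabilities (length N).
#' @param A N x N transition matrix.
#' @param B N x M emission matrix.
#' @return A list of class `hmm_model`.
#' @export
hmm_model <- function(pi, A, B) {
  pi <- as.numeric(pi); A <- as.matrix(A); B <- as.matrix(B)
  N <- length(pi)
  if (!all(dim(A) == c(N, N))) stop("A must be N x N")
  if (nrow(B) != N) stop("B must have N rows")
  if (any(pi < 0) || any(A < 0) || any(B < 0))
    stop("probabilities must be nonnegative")
  if (abs(sum(pi) - 1) > 1e-9 || any(abs(rowSums(A) - 1) > 1e-9) ||
      any(abs(rowSums(B) - 1) > 1e-9))
    stop("pi and the rows of A and B must sum to 1")
  structure(list(N = N, M = ncol(B), pi = pi, A = A, B = B),
            class = "hmm_model")
}

#' Forward algorithm: log P(O | lambda)
#'
#' Scaled forward recursion: `alpha_1(j) = pi_j b_j(o_1)`,
#' `alpha_t(j) = sum_i alpha_{t-1}(i) a_ij b_j(o_t)`, and
#' `P(O|lambda) = sum_j alpha_T(j)`, accumulated in log space through
#' per-step normalisation.
#'
#' @param model an [hmm_model()].
#' @param obs integer symbol sequence in `1..M`.
#' @return Log-likelihood `log P(O | lambda)`.
#' @export
hmm_forward <- function(model, obs) {
  obs <- as.integer(obs)
  if (!length(obs)) stop("observation sequence is empty")
  if (any(obs < 1L | obs > model$M)) stop("symbols out of range 1..M")
  alpha <- model$pi * model$B[, obs[1]]
  ll <- 0
  s <- sum(alpha)
  if (s == 0) return(-Inf)
  ll <- log(s); alpha <- alpha / s
  for (t in seq_along(obs)[-1]) {
    alpha <- drop(alpha %*% model$A) * model$B[, obs[t]]
    s <- sum(alpha)
    if (s == 0) return(-Inf)
    ll <- ll + log(s)
    alpha <- alpha / s
  }
  ll
}

#' Backward algorithm: the beta table
#'
#' `beta_T(i) = 1`;
#' `beta_t(i) = sum_j a_ij b_j(o_{t+1}) beta_{t+1}(j)`.  Returned unscaled,
#' so `sum_i pi_i b_i(o_1) beta_1(i) = P(O | lambda)`; intended for short
#' sequences (the trainer uses a scaled variant internally).
#'
#' @param model an [hmm_model()].
#' @param obs integer symbol sequence.
#' @return A T x N matrix of backward probabilities.
#' @export
hmm_backward <- function(model, obs) {
  obs <- as.integer(obs)
  if (!length(obs)) stop("observation sequence is empty")
  T_ <- length(obs); N <- model$N
  beta <- matrix(0, T_, N)
  beta[T_, ] <- 1
  if (T_ > 1L) for (t in (T_ - 1L):1L)
    beta[t, ] <- drop(model$A %*% (model$B[, obs[t + 1L]] * beta[t + 1L, ]))
  beta
}

#' Baum-Welch estimation of a discrete HMM
#'
#' Multi-sequence EM re-estimation with per-step scaling.  The total
#' log-likelihood is non-decreasing across iterations; training stops when
#' the improvement falls below `tol` or after `max_iter` iterations.
#'
#' @param obs_set nonempty list of integer symbol sequences.
#' @param N number of hidden states.
#' @param M number of observation symbols.
#' @param seed seed for the random initialisation.
#' @param max_iter,tol stopping rule.
#' @param topology `"lr"` (default): left-to-right chain with self-loops,
#'   start in state 1 — motion phases progress monotonically; `"ergodic"`:
#'   fully connected.
#' @return An [hmm_model()] with an attached `loglik_trace` attribute.
#' @export
hmm_fit <- function(obs_set, N = 5L, M, seed = 1L, max_iter = 100L,
                    tol = 1e-6, topology = c("lr", "ergodic")) {
  if (!length(obs_set)) stop("empty training set")
  topology <- match.arg(topology)
  obs_set <- lapply(obs_set, as.integer)
  if (missing(M)) M <- max(unlist(obs_set))
  N <- as.integer(N); M <- as.integer(M)
  set.seed(seed)

  rdirich <- function(n) { g <- stats::rgamma(n, 5, 1); g / sum(g) }
  if (topology == "lr") {
    pi <- c(1, rep(0, N - 1L))
    A <- matrix(0, N, N)
    for (i in seq_len(N)) {
      if (i < N) { p <- runif(1, 0.4, 0.8); A[i, i] <- p; A[i, i + 1L] <- 1 - p }
      else A[i, i] <- 1
    }
  } else {
    pi <- rdirich(N)
    A <- t(vapply(seq_len(N), function(i) rdirich(N), numeric(N)))
  }
  B <- t(vapply(seq_len(N), function(i) rdirich(M), numeric(M)))

  loglik_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    pi_num <- numeric(N)
    A_num <- matrix(0, N, N); A_den <- numeric(N)
    B_num <- matrix(0, N, M); B_den <- numeric(N)
    total_ll <- 0
    for (obs in obs_set) {
      T_ <- length(obs)
      # scaled forward/backward
      alpha <- matrix(0, T_, N); cvec <- numeric(T_)
      a <- pi * B[, obs[1]]
      cvec[1] <- sum(a); if (cvec[1] == 0) cvec[1] <- .Machine$double.xmin
      alpha[1, ] <- a / cvec[1]
      if (T_ > 1L) for (t in 2:T_) {
        a <- drop(alpha[t - 1L, ] %*% A) * B[, obs[t]]
        cvec[t] <- sum(a); if (cvec[t] == 0) cvec[t] <- .Machine$double.xmin
        alpha[t, ] <- a / cvec[t]
      }
      beta <- matrix(0, T_, N)
      beta[T_, ] <- 1
      if (T_ > 1L) for (t in (T_ - 1L):1L)
        beta[t, ] <- drop(A %*% (B[, obs[t + 1L]] * beta[t + 1L, ])) /
          cvec[t + 1L]
      total_ll <- total_ll + sum(log(cvec))

      gamma <- alpha * beta
      gamma <- gamma / pmax(rowSums(gamma), .Machine$double.xmin)
      pi_num <- pi_num + gamma[1, ]
      for (t in seq_len(T_))
        B_num[, obs[t]] <- B_num[, obs[t]] + gamma[t, ]
      B_den <- B_den + colSums(gamma)
      if (T_ > 1L) for (t in seq_len(T_ - 1L)) {
        xi <- (alpha[t, ] %o% (B[, obs[t + 1L]] * beta[t + 1L, ])) * A /
          cvec[t + 1L]
        A_num <- A_num + xi
        A_den <- A_den + rowSums(xi)
      }
    }
    loglik_trace <- c(loglik_trace, total_ll)
    mask <- A > 0  # preserve structural zeros of the topology
    pi_new <- pi_num / length(obs_set)
    A_new <- ifelse(mask, A_num, 0)
    rs <- rowSums(A_new)
    A_new <- A_new / ifelse(rs > 0, rs, 1)
    A_new[rs == 0, ] <- A[rs == 0, ]
    B_new <- (B_num + 1e-10) / (B_den + M * 1e-10)
    pi <- pi_new / sum(pi_new); A <- A_new; B <- B_new
    if (iter > 1L) {
      d <- loglik_trace[iter] - loglik_trace[iter - 1L]
      if (abs(d) < tol) break
    }
  }
  m <- hmm_model(pi, A, B)
  attr(m, "loglik_trace") <- loglik_trace
  m
}

#' Classify an observation sequence with per-class HMMs
#'
#' The class whose model gives the highest forward log-likelihood wins; ties
#' go to the lowest class id (list order).
#'
#' @param models nonempty (optionally named) list of [hmm_model()]s.
#' @param obs integer symbol sequence.
#' @return The winning class: the element name if `models` is named, else the
#'   index.
#' @export
hmm_classify <- function(models, obs) {
  if (!length(models)) stop("no models supplied")
  ll <- vapply(models, hmm_forward, numeric(1), obs = obs)
  best <- which.max(ll)  # which.max takes the first (lowest id) on ties
  if (!is.null(names(models))) names(models)[best] else best
}
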