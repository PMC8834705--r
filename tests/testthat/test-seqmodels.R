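# --- vector quantisation ----------------------------------------------------

test_that("the codebook segments distinct pose clusters and is deterministic", {
  cfg <- tiny_config(seed = 2)
  q1 <- motion_quaternions(make_teacher_template(1, cfg)$motion)
  q2 <- motion_quaternions(make_teacher_template(2, cfg)$motion)
  cb <- fit_codebook(list(q1, q2), M = 4, seed = 3)
  expect_equal(nrow(cb$centroids), 4L)
  expect_identical(quantize(q1, cb), quantize(q1, cb))

  # two well-separated single-pose motions, M = 2: symbols segment them
  mk <- function(w) structure(array(rep(c(w, sqrt(1 - w^2), 0, 0),
                                        each = 10), c(10, 1, 4)),
                              class = "quaternion_sequence")
  qa <- mk(1); qb <- mk(0.2)
  cb2 <- fit_codebook(list(qa, qb), M = 2, seed = 1)
  sa <- unique(quantize(qa, cb2)); sb <- unique(quantize(qb, cb2))
  expect_length(sa, 1); expect_length(sb, 1)
  expect_false(sa == sb)

  # constant motion: codebook collapses to one symbol with a warning
  expect_warning(cb1 <- fit_codebook(list(qa), M = 8, seed = 1), "reduced")
  expect_true(all(quantize(qa, cb1) == 1L))
})

# --- HMM --------------------------------------------------------------------

test_that("the forward algorithm matches closed forms and the path-sum oracle", {
  # N = 1 degenerate chain
  m1 <- hmm_model(1, matrix(1), matrix(c(0.7, 0.3), 1))
  obs <- c(1L, 1L, 2L)
  expect_equal(hmm_forward(m1, obs), log(0.7 * 0.7 * 0.3), tolerance = 1e-12)
  # T = 1 reduces to sum_j pi_j b_j(o1)
  set.seed(4)
  m2 <- random_hmm(3, 2)
  expect_equal(hmm_forward(m2, 2L), log(sum(m2$pi * m2$B[, 2])),
               tolerance = 1e-12)
  # random models vs exhaustive enumeration
  set.seed(8)
  for (i in 1:40) {
    N <- sample(2:4, 1); M <- sample(2:4, 1); T_ <- sample(1:5, 1)
    m <- random_hmm(N, M)
    o <- sample(seq_len(M), T_, replace = TRUE)
    expect_equal(hmm_forward(m, o), brute_hmm_loglik(m, o),
                 tolerance = 1e-10)
  }
  expect_error(hmm_forward(m2, integer()), "empty")
  expect_error(hmm_forward(m2, 5L), "range")
})

test_that("the backward recursion satisfies its boundary and consistency identities", {
  set.seed(12)
  for (i in 1:20) {
    m <- random_hmm(sample(2:4, 1), sample(2:4, 1))
    o <- sample(seq_len(m$M), sample(2:5, 1), replace = TRUE)
    beta <- hmm_backward(m, o)
    expect_equal(unname(beta[length(o), ]), rep(1, m$N))
    expect_equal(log(sum(m$pi * m$B[, o[1]] * beta[1, ])),
                 hmm_forward(m, o), tolerance = 1e-10)
  }
  # N = 1: beta_t is the product of later emission probabilities
  m1 <- hmm_model(1, matrix(1), matrix(c(0.6, 0.4), 1))
  b <- hmm_backward(m1, c(1L, 2L, 1L))
  expect_equal(b[, 1], c(0.4 * 0.6, 0.6, 1))
})

test_that("Baum-Welch improves the likelihood and recovers a planted chain", {
  # single repeated symbol, N = 1: emissions concentrate on that symbol
  fit1 <- hmm_fit(list(rep(1L, 20), rep(1L, 15)), N = 1, M = 2, seed = 1,
                  max_iter = 20, topology = "ergodic")
  expect_gt(fit1$B[1, 1], 0.999)

  set.seed(21)
  A0 <- rbind(c(0.85, 0.15), c(0.25, 0.75))
  B0 <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  gen <- function(T_) {
    s <- sample(1:2, 1)
    o <- integer(T_)
    for (t in seq_len(T_)) {
      o[t] <- sample(1:2, 1, prob = B0[s, ])
      if (t < T_) s <- sample(1:2, 1, prob = A0[s, ])
    }
    o
  }
  obs_set <- lapply(1:50, function(i) gen(40))
  fit <- hmm_fit(obs_set, N = 2, M = 2, seed = 2, max_iter = 100,
                 topology = "ergodic")
  tr <- attr(fit, "loglik_trace")
  expect_true(all(diff(tr) > -1e-8))
  perm <- if (fit$B[1, 1] > fit$B[2, 1]) 1:2 else 2:1
  expect_lt(max(abs(fit$A[perm, perm] - A0)), 0.1)
  expect_error(hmm_fit(list(), N = 2, M = 2), "empty")
})

test_that("per-class HMM likelihood classification picks the generating model", {
  set.seed(31)
  mA <- hmm_model(c(1, 0), rbind(c(0.9, 0.1), c(0, 1)),
                  rbind(c(0.95, 0.05), c(0.05, 0.95)))
  mB <- hmm_model(c(1, 0), rbind(c(0.9, 0.1), c(0, 1)),
                  rbind(c(0.05, 0.95), c(0.95, 0.05)))
  obsA <- c(1L, 1L, 1L, 2L, 2L)
  expect_equal(hmm_classify(list(A = mA, B = mB), obsA), "A")
  expect_equal(hmm_classify(list(only = mA), obsA), "only")
  # identical models: tie resolves to the first class
  expect_equal(hmm_classify(list(mA, mA), obsA), 1L)
})

test_that("HMM models enforce their stochasticity invariants", {
  expect_error(hmm_model(c(0.5, 0.4), diag(2), diag(2)), "sum to 1")
  expect_error(hmm_model(1, matrix(1), matrix(c(-0.1, 1.1), 1)),
               "nonnegative")
})

# --- recurrent models -------------------------------------------------------

zeroed <- function(params) rapply(params, function(m) 0 * m, how = "replace")

test_that("zero-weight closed forms hold for the LSTM and GRU cells", {
  x <- matrix(rnorm(10), 5, 2)
  for (kind in c("lstm", "gru", "bilstm")) {
    params <- zeroed(motionseq:::rnn_init(kind, 2L, 3L, 2L, seed = 1))
    hf <- motionseq:::rnn_hidden_final(params, kind, x)
    expect_equal(hf$hfin, rep(0, length(hf$hfin)), info = kind)
  }
  # gru internals: zero weights give z = 0.5 and htilde = 0 at every step
  pg <- zeroed(motionseq:::gru_init(2L, 3L))
  cache <- motionseq:::gru_pass(pg, x)
  expect_true(all(cache$Z_ == 0.5))
  expect_true(all(cache$G_ == 0))
})

test_that("a hand-set one-unit LSTM reproduces symbolic two-step evaluation", {
  w <- list(W_f = matrix(c(0.5, 1), 1), b_f = 0.1,
            W_i = matrix(c(-0.3, 0.8), 1), b_i = -0.2,
            W_o = matrix(c(0.2, -0.5), 1), b_o = 0.3,
            W_c = matrix(c(1, 0.4), 1), b_c = 0)
  x <- matrix(c(0.7, -0.2), 2, 1)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- 0; C <- 0
  for (t in 1:2) {
    z <- c(h, x[t, 1])
    f <- sig(sum(w$W_f * z) + w$b_f)
    i <- sig(sum(w$W_i * z) + w$b_i)
    o <- sig(sum(w$W_o * z) + w$b_o)
    g <- tanh(sum(w$W_c * z) + w$b_c)
    C <- f * C + i * g
    h <- o * tanh(C)
  }
  cache <- motionseq:::lstm_pass(w, x)
  expect_equal(cache$H[3, 1], h, tolerance = 1e-14)
  expect_equal(cache$C[3, 1], C, tolerance = 1e-14)
})

test_that("gate outputs stay in their ranges on random inputs", {
  set.seed(40)
  x <- matrix(rnorm(12), 6, 2)
  pl <- motionseq:::rnn_init("lstm", 2L, 4L, 2L, seed = 2)
  cl <- motionseq:::lstm_pass(pl$fwd, x)
  expect_true(all(cl$F_ > 0 & cl$F_ < 1))
  expect_true(all(cl$I_ > 0 & cl$I_ < 1))
  expect_true(all(cl$O_ > 0 & cl$O_ < 1))
  expect_true(all(cl$G_ > -1 & cl$G_ < 1))
  pg <- motionseq:::rnn_init("gru", 2L, 4L, 2L, seed = 2)
  cg <- motionseq:::gru_pass(pg$fwd, x)
  expect_true(all(cg$R_ > 0 & cg$R_ < 1 & cg$Z_ > 0 & cg$Z_ < 1))
})

test_that("analytic BPTT gradients match central finite differences", {
  set.seed(3)
  seqs <- list(matrix(rnorm(4), 2, 2), matrix(rnorm(4), 2, 2))
  y <- c(1L, 2L)
  for (kind in c("lstm", "gru", "bilstm")) {
    params <- motionseq:::rnn_init(kind, 2L, 3L, 2L, seed = 5)
    an <- unlist(motionseq:::rnn_loss_grad(params, kind, seqs, y, 2L)$grads)
    num <- fd_rnn_gradient(params, kind, seqs, y, 2L)
    rel <- abs(an - num) / pmax(abs(an), abs(num), 1e-6)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("a BiLSTM with tied directions treats palindromes symmetrically", {
  params <- motionseq:::rnn_init("bilstm", 1L, 3L, 2L, seed = 6)
  params$bwd <- params$fwd
  x <- matrix(c(0.3, -1, 0.5, -1, 0.3), ncol = 1)
  hf <- motionseq:::rnn_hidden_final(params, "bilstm", x)
  expect_equal(hf$hfin[1:3], hf$hfin[4:6], tolerance = 1e-14)
})

test_that("recurrent training separates constant +1/-1 sequences", {
  set.seed(50)
  seqs <- c(lapply(1:6, function(i) matrix(1 + rnorm(8, 0, 0.05), 8, 1)),
            lapply(1:6, function(i) matrix(-1 + rnorm(8, 0, 0.05), 8, 1)))
  y <- rep(c("pos", "neg"), each = 6)
  for (kind in c("lstm", "gru")) {
    m <- rnn_fit(kind, seqs, y, hidden_dim = 4, epochs = 200,
                 learning_rate = 0.2, seed = 7)
    expect_equal(accuracy(y, predict(m, seqs)), 100, info = kind)
    expect_lt(tail(m$loss_trace, 1), m$loss_trace[1])
    expect_true(all(is.finite(m$loss_trace)))
  }
  # zero epochs: model predicts from its initial weights
  m0 <- rnn_fit("gru", seqs, y, hidden_dim = 4, epochs = 0, seed = 7)
  expect_length(predict(m0, seqs), 12)
  expect_error(rnn_fit("lstm", seqs, rep("pos", 12)), "two classes")
  expect_error(rnn_forward(m0, matrix(numeric(0), 0, 1)), "empty")
})
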