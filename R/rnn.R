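# Minimal recurrent sequence classifiers: LSTM, BiLSTM, GRU cells with
# full-batch backpropagation through time.  Sequences are frames x input_dim
# matrices processed at native length; the readout is an affine map of the
# final hidden state (concatenated final states for BiLSTM).

sigmoid <- function(x) 1 / (1 + exp(-x))

# parameter initialisation -----------------------------------------------

lstm_init <- function(p, h, seed_offset = 0L) {
  rw <- function(r, c) matrix(runif(r * c, -0.5, 0.5) / sqrt(c), r, c)
  list(W_f = rw(h, h + p), b_f = numeric(h),
       W_i = rw(h, h + p), b_i = numeric(h),
       W_o = rw(h, h + p), b_o = numeric(h),
       W_c = rw(h, h + p), b_c = numeric(h))
}

gru_init <- function(p, h) {
  rw <- function(r, c) matrix(runif(r * c, -0.5, 0.5) / sqrt(c), r, c)
  list(W_r = rw(h, h + p), b_r = numeric(h),
       W_z = rw(h, h + p), b_z = numeric(h),
       W_h = rw(h, h + p), b_h = numeric(h))
}

rnn_init <- function(kind, input_dim, hidden_dim, n_classes, seed) {
  set.seed(seed)
  p <- input_dim; h <- hidden_dim
  rw <- function(r, c) matrix(runif(r * c, -0.5, 0.5) / sqrt(c), r, c)
  cell <- switch(kind,
    lstm = list(fwd = lstm_init(p, h)),
    bilstm = list(fwd = lstm_init(p, h), bwd = lstm_init(p, h)),
    gru = list(fwd = gru_init(p, h)))
  readout_dim <- if (kind == "bilstm") 2L * h else h
  c(cell, list(V = rw(n_classes, readout_dim), c0 = numeric(n_classes)))
}

# single-direction passes with caches for BPTT ---------------------------

lstm_pass <- function(w, x) {
  T_ <- nrow(x); h <- length(w$b_f)
  H <- matrix(0, T_ + 1L, h); C <- matrix(0, T_ + 1L, h)
  F_ <- I_ <- O_ <- G_ <- matrix(0, T_, h)
  for (t in seq_len(T_)) {
    z <- c(H[t, ], x[t, ])
    f <- sigmoid(drop(w$W_f %*% z) + w$b_f)
    i <- sigmoid(drop(w$W_i %*% z) + w$b_i)
    o <- sigmoid(drop(w$W_o %*% z) + w$b_o)
    g <- tanh(drop(w$W_c %*% z) + w$b_c)
    C[t + 1L, ] <- f * C[t, ] + i * g
    H[t + 1L, ] <- o * tanh(C[t + 1L, ])
    F_[t, ] <- f; I_[t, ] <- i; O_[t, ] <- o; G_[t, ] <- g
  }
  list(H = H, C = C, F_ = F_, I_ = I_, O_ = O_, G_ = G_, x = x)
}

lstm_backward <- function(w, cache, dh_T) {
  x <- cache$x; T_ <- nrow(x); h <- length(dh_T); p <- ncol(x)
  g <- list(W_f = 0 * w$W_f, b_f = numeric(h), W_i = 0 * w$W_i,
            b_i = numeric(h), W_o = 0 * w$W_o, b_o = numeric(h),
            W_c = 0 * w$W_c, b_c = numeric(h))
  dh <- dh_T; dC <- numeric(h)
  for (t in T_:1L) {
    f <- cache$F_[t, ]; i <- cache$I_[t, ]
    o <- cache$O_[t, ]; gg <- cache$G_[t, ]
    Ct <- cache$C[t + 1L, ]; Cp <- cache$C[t, ]
    tC <- tanh(Ct)
    do_ <- dh * tC
    dC <- dC + dh * o * (1 - tC^2)
    df_ <- dC * Cp; di_ <- dC * gg; dg_ <- dC * i
    dCp <- dC * f
    af <- df_ * f * (1 - f); ai <- di_ * i * (1 - i)
    ao <- do_ * o * (1 - o); ag <- dg_ * (1 - gg^2)
    z <- c(cache$H[t, ], x[t, ])
    g$W_f <- g$W_f + af %o% z; g$b_f <- g$b_f + af
    g$W_i <- g$W_i + ai %o% z; g$b_i <- g$b_i + ai
    g$W_o <- g$W_o + ao %o% z; g$b_o <- g$b_o + ao
    g$W_c <- g$W_c + ag %o% z; g$b_c <- g$b_c + ag
    dz <- drop(crossprod(w$W_f, af) + crossprod(w$W_i, ai) +
               crossprod(w$W_o, ao) + crossprod(w$W_c, ag))
    dh <- dz[seq_len(h)]
    dC <- dCp
  }
  g
}

gru_pass <- function(w, x) {
  T_ <- nrow(x); h <- length(w$b_r)
  H <- matrix(0, T_ + 1L, h)
  R_ <- Z_ <- G_ <- matrix(0, T_, h)
  for (t in seq_len(T_)) {
    z <- c(H[t, ], x[t, ])
    r <- sigmoid(drop(w$W_r %*% z) + w$b_r)
    zt <- sigmoid(drop(w$W_z %*% z) + w$b_z)
    zh <- c(r * H[t, ], x[t, ])
    g <- tanh(drop(w$W_h %*% zh) + w$b_h)
    H[t + 1L, ] <- (1 - zt) * H[t, ] + zt * g
    R_[t, ] <- r; Z_[t, ] <- zt; G_[t, ] <- g
  }
  list(H = H, R_ = R_, Z_ = Z_, G_ = G_, x = x)
}

gru_backward <- function(w, cache, dh_T) {
  x <- cache$x; T_ <- nrow(x); h <- length(dh_T)
  g <- list(W_r = 0 * w$W_r, b_r = numeric(h), W_z = 0 * w$W_z,
            b_z = numeric(h), W_h = 0 * w$W_h, b_h = numeric(h))
  dh <- dh_T
  for (t in T_:1L) {
    r <- cache$R_[t, ]; zt <- cache$Z_[t, ]; gg <- cache$G_[t, ]
    hp <- cache$H[t, ]
    dzt <- dh * (gg - hp)
    dg <- dh * zt
    dhp <- dh * (1 - zt)
    ag <- dg * (1 - gg^2)
    zh <- c(r * hp, x[t, ])
    g$W_h <- g$W_h + ag %o% zh; g$b_h <- g$b_h + ag
    drh <- drop(crossprod(w$W_h, ag))[seq_len(h)]
    dr <- drh * hp
    dhp <- dhp + drh * r
    ar <- dr * r * (1 - r); az <- dzt * zt * (1 - zt)
    z <- c(hp, x[t, ])
    g$W_r <- g$W_r + ar %o% z; g$b_r <- g$b_r + ar
    g$W_z <- g$W_z + az %o% z; g$b_z <- g$b_z + az
    dz <- drop(crossprod(w$W_r, ar) + crossprod(w$W_z, az))
    dh <- dhp + dz[seq_len(h)]
  }
  g
}

# readout + loss ----------------------------------------------------------

rnn_hidden_final <- function(params, kind, x) {
  if (kind == "lstm") {
    cache <- lstm_pass(params$fwd, x)
    list(hfin = cache$H[nrow(x) + 1L, ], caches = list(fwd = cache))
  } else if (kind == "gru") {
    cache <- gru_pass(params$fwd, x)
    list(hfin = cache$H[nrow(x) + 1L, ], caches = list(fwd = cache))
  } else {  # bilstm: forward pass plus a pass over the reversed sequence
    cf <- lstm_pass(params$fwd, x)
    xr <- x[rev(seq_len(nrow(x))), , drop = FALSE]
    cb <- lstm_pass(params$bwd, xr)
    list(hfin = c(cf$H[nrow(x) + 1L, ], cb$H[nrow(x) + 1L, ]),
         caches = list(fwd = cf, bwd = cb))
  }
}

softmax <- function(s) { s <- s - max(s); e <- exp(s); e / sum(e) }

# mean cross-entropy loss and parameter gradients over a training set
rnn_loss_grad <- function(params, kind, seqs, y_int, n_classes,
                          want_grad = TRUE) {
  n <- length(seqs)
  loss <- 0
  grads <- if (want_grad) rapply(params, function(m) 0 * m, how = "replace")
  for (s in seq_len(n)) {
    x <- seqs[[s]]
    fw <- rnn_hidden_final(params, kind, x)
    scores <- drop(params$V %*% fw$hfin) + params$c0
    pr <- softmax(scores)
    loss <- loss - log(max(pr[y_int[s]], 1e-300)) / n
    if (!want_grad) next
    ds <- pr
    ds[y_int[s]] <- ds[y_int[s]] - 1
    ds <- ds / n
    grads$V <- grads$V + ds %o% fw$hfin
    grads$c0 <- grads$c0 + ds
    dh <- drop(crossprod(params$V, ds))
    if (kind == "lstm") {
      gf <- lstm_backward(params$fwd, fw$caches$fwd, dh)
      for (nm in names(gf)) grads$fwd[[nm]] <- grads$fwd[[nm]] + gf[[nm]]
    } else if (kind == "gru") {
      gf <- gru_backward(params$fwd, fw$caches$fwd, dh)
      for (nm in names(gf)) grads$fwd[[nm]] <- grads$fwd[[nm]] + gf[[nm]]
    } else {
      h <- ncol(params$fwd$W_f)  # not hidden size; recompute below
      hdim <- length(params$fwd$b_f)
      gf <- lstm_backward(params$fwd, fw$caches$fwd, dh[seq_len(hdim)])
      gb <- lstm_backward(params$bwd, fw$caches$bwd, dh[hdim + seq_len(hdim)])
      for (nm in names(gf)) {
        grads$fwd[[nm]] <- grads$fwd[[nm]] + gf[[nm]]
        grads$bwd[[nm]] <- grads$bwd[[nm]] + gb[[nm]]
      }
    }
  }
  list(loss = loss, grads = grads)
}

#' Forward pass of a recurrent sequence classifier
#'
#' Runs the cell recurrence from zero initial state over the (normalised)
#' input sequence and returns the class scores of the affine readout of the
#' final hidden state.  For BiLSTM the sequence is additionally processed
#' back-to-front by the second cell and the two final states are
#' concatenated.
#'
#' @param model an `rnn_model` from [rnn_fit()].
#' @param x numeric matrix, frames x input_dim (a flattened keyframe
#'   quaternion sequence).
#' @return Named numeric vector of class scores.
#' @export
rnn_forward <- function(model, x) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("input sequence is empty")
  if (ncol(x) != model$input_dim)
    stop("input dimension does not match the model")
  x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  fw <- rnn_hidden_final(model$params, model$kind, x)
  scores <- drop(model$params$V %*% fw$hfin) + model$params$c0
  names(scores) <- model$classes
  scores
}

#' Train a recurrent sequence classifier
#'
#' Full-batch gradient descent on softmax cross-entropy via backpropagation
#' through time, with gradient clipping at global norm 5.  Input dimensions
#' are z-score normalised over the training set.  Deterministic given `seed`.
#'
#' @param kind `"lstm"`, `"bilstm"` or `"gru"`.
#' @param sequences list of frames x input_dim matrices (variable lengths).
#' @param labels one label per sequence; at least two classes.
#' @param hidden_dim hidden state size (default 32).
#' @param epochs training epochs (default 200).
#' @param learning_rate gradient-descent step (default 0.01).
#' @param seed integer seed for the weight initialisation.
#' @return An object of class `rnn_model` (with a `loss_trace`).
#' @export
rnn_fit <- function(kind = c("lstm", "bilstm", "gru"), sequences, labels,
                    hidden_dim = 32L, epochs = 200L, learning_rate = 0.01,
                    seed = 1L) {
  kind <- match.arg(kind)
  if (!length(sequences)) stop("no training sequences")
  y <- droplevels(factor(labels))
  if (nlevels(y) < 2L) stop("training requires at least two classes")
  seqs <- lapply(sequences, as.matrix)
  p <- ncol(seqs[[1]])
  allx <- do.call(rbind, seqs)
  ctr <- colMeans(allx); scl <- apply(allx, 2, sd); scl[scl == 0] <- 1
  seqs <- lapply(seqs, function(x) sweep(sweep(x, 2, ctr), 2, scl, "/"))
  K <- nlevels(y)
  params <- rnn_init(kind, p, as.integer(hidden_dim), K, seed)
  y_int <- as.integer(y)
  trace <- numeric(epochs)
  for (e in seq_len(epochs)) {
    lg <- rnn_loss_grad(params, kind, seqs, y_int, K)
    if (!is.finite(lg$loss))
      stop("training diverged (non-finite loss); try a smaller learning_rate")
    trace[e] <- lg$loss
    flat <- unlist(lg$grads)
    nrm <- sqrt(sum(flat^2))
    scale_g <- if (nrm > 5) 5 / nrm else 1
    params <- clone_update(params, lg$grads, learning_rate * scale_g)
  }
  structure(list(kind = kind, input_dim = p, hidden_dim = as.integer(hidden_dim),
                 params = params, classes = levels(y), center = ctr,
                 scale = scl, loss_trace = trace),
            class = "rnn_model")
}

# elementwise params <- params - lr * grads, preserving the nested shape
clone_update <- function(params, grads, lr) {
  for (nm in names(params)) {
    if (is.list(params[[nm]])) {
      for (nm2 in names(params[[nm]]))
        params[[nm]][[nm2]] <- params[[nm]][[nm2]] - lr * grads[[nm]][[nm2]]
    } else {
      params[[nm]] <- params[[nm]] - lr * grads[[nm]]
    }
  }
  params
}

#' Predict classes for sequences with a trained recurrent model
#'
#' @param object an `rnn_model`.
#' @param newdata list of frames x input_dim matrices.
#' @param ... unused.
#' @return Factor of predicted labels.
#' @export
predict.rnn_model <- function(object, newdata, ...) {
  out <- vapply(newdata, function(x) {
    s <- rnn_forward(object, x)
    object$classes[which.max(s)]
  }, character(1))
  factor(out, levels = object$classes)
}
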