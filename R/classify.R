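#' Classifier specification
#'
#' Seven feature-vector classifier kinds share one training surface.  The
#' classical ones are delegated to their standard implementations
#' (`e1071::svm`, `e1071::naiveBayes`, `nnet::multinom`, `rpart::rpart`);
#' k-NN, the back-propagation network (BPNN) and the radial-basis-function
#' network (RBFNN) are implemented here.
#'
#' @param method one of `"knn"`, `"svm"`, `"nb"`, `"logistic"`, `"dtree"`,
#'   `"bpnn"`, `"rbfnn"` (stored as the spec's `kind`; the formal is named
#'   `method` so hyperparameters like `k` pass cleanly through `...`).
#' @param ... kind-specific hyperparameters overriding the defaults:
#'   `k` (knn, 3); `kernel`, `C` (svm, radial / 1); `depth` (dtree,
#'   unlimited); `hidden_units` (bpnn, 16), `epochs` (500), `learning_rate`
#'   (0.01), `seed` (1); `n_centers` (rbfnn, 8), `d` (width; default the
#'   median pairwise centre distance), `seed`.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(method = c("knn", "svm", "nb", "logistic",
                                       "dtree", "bpnn", "rbfnn"), ...) {
  kind <- match.arg(method)
  defaults <- switch(kind,
    knn = list(k = 3L),
    svm = list(kernel = "radial", C = 1),
    nb = list(),
    logistic = list(decay = 1e-4, maxit = 500L),
    dtree = list(depth = 30L),
    bpnn = list(hidden_units = 16L, epochs = 500L, learning_rate = 0.01,
                seed = 1L),
    rbfnn = list(n_centers = 8L, d = NULL, seed = 1L))
  hp <- utils::modifyList(defaults, list(...))
  if (kind == "knn" && (!is.numeric(hp$k) || hp$k < 1))
    stop("knn requires k >= 1")
  if (kind == "bpnn" && hp$hidden_units < 1)
    stop("bpnn requires at least one hidden unit")
  if (kind == "rbfnn" && hp$n_centers < 1)
    stop("rbfnn requires at least one centre")
  structure(list(kind = kind, hyperparams = hp), class = "classifier_spec")
}

#' Tangent-sigmoid activation
#'
#' `f(x) = 2 / (1 + exp(-2x)) - 1`, the hidden-layer activation of the BPNN.
#'
#' @param x numeric.
#' @return Values in (-1, 1).
#' @export
tansig <- function(x) 2 / (1 + exp(-2 * x)) - 1

#' Train a classifier on feature vectors
#'
#' @param spec a [classifier_spec()].
#' @param X numeric matrix of feature vectors (rows = samples).
#' @param y labels (factor or coercible); discriminative kinds require at
#'   least two classes.
#' @return An object of class `trained_classifier`.
#' @export
train_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("features must be finite")
  y <- factor(y)
  if (nrow(X) != length(y)) stop("X and y lengths differ")
  if (nlevels(droplevels(y)) < 2L)
    stop("training labels contain a single class; at least two are required")
  y <- droplevels(y)
  hp <- spec$hyperparams

  fit <- switch(spec$kind,
    knn = list(X = X, y = y, k = as.integer(hp$k)),
    svm = e1071::svm(X, y, kernel = hp$kernel, cost = hp$C, scale = FALSE),
    nb = e1071::naiveBayes(X, y),
    logistic = {
      df <- data.frame(y = y, X)
      set.seed(1L)
      nnet::multinom(y ~ ., data = df, trace = FALSE, decay = hp$decay,
                     maxit = hp$maxit)
    },
    dtree = {
      df <- data.frame(y = y, X)
      rpart::rpart(y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(minsplit = 2, minbucket = 1,
                                                  cp = 0, xval = 0,
                                                  maxdepth = hp$depth))
    },
    bpnn = fit_bpnn(X, y, hp),
    rbfnn = fit_rbfnn(X, y, hp))

  structure(list(spec = spec, fit = fit, classes = levels(y),
                 n_features = ncol(X)),
            class = "trained_classifier")
}

#' Predict labels with a trained classifier
#'
#' k-NN voting ties are broken towards the tied label with the smallest mean
#' neighbour distance, then the lowest label.
#'
#' @param object a `trained_classifier`.
#' @param newdata numeric matrix of feature vectors.
#' @param ... unused.
#' @return Factor of predicted labels (levels = training classes).
#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (nrow(X) == 0L)
    return(factor(character(), levels = object$classes))
  if (ncol(X) != object$n_features)
    stop("feature dimension does not match training (", object$n_features, ")")
  storage.mode(X) <- "double"
  out <- switch(object$spec$kind,
    knn = predict_knn(object$fit, X),
    svm = as.character(predict(object$fit, X)),
    nb = as.character(predict(object$fit, X)),
    logistic = as.character(predict(object$fit,
                                    data.frame(X, check.names = TRUE))),
    dtree = as.character(predict(object$fit,
                                 data.frame(X, check.names = TRUE),
                                 type = "class")),
    bpnn = predict_bpnn(object$fit, X),
    rbfnn = predict_rbfnn(object$fit, X))
  factor(out, levels = object$classes)
}

# ---- k-NN ------------------------------------------------------------------

predict_knn <- function(fit, X) {
  k <- min(fit$k, nrow(fit$X))
  tr2 <- rowSums(fit$X^2)
  out <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    d2 <- tr2 - 2 * drop(fit$X %*% X[i, ]) + sum(X[i, ]^2)
    nn <- order(d2)[seq_len(k)]
    votes <- table(fit$y[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      meand <- vapply(top, function(lb)
        mean(sqrt(pmax(d2[nn][fit$y[nn] == lb], 0))), numeric(1))
      top <- top[meand == min(meand)]
      top <- top[order(match(top, levels(fit$y)))][1]  # lowest label
    }
    out[i] <- top
  }
  out
}

# ---- BPNN (three-layer back-propagation network) ---------------------------
# Input layer sized to the feature dimension, one tangent-sigmoid hidden
# layer, softmax output; full-batch gradient descent on cross-entropy.

fit_bpnn <- function(X, y, hp) {
  set.seed(hp$seed)
  n <- nrow(X); p <- ncol(X); h <- as.integer(hp$hidden_units)
  K <- nlevels(y)
  ctr <- colMeans(X); scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  Y <- diag(K)[as.integer(y), , drop = FALSE]
  W1 <- matrix(runif(h * p, -0.5, 0.5) / sqrt(p), h, p); b1 <- numeric(h)
  W2 <- matrix(runif(K * h, -0.5, 0.5) / sqrt(h), K, h); b2 <- numeric(K)
  lr <- hp$learning_rate
  loss <- numeric(hp$epochs)
  for (e in seq_len(hp$epochs)) {
    A1 <- tansig(Xs %*% t(W1) + rep(b1, each = n))        # n x h
    S <- A1 %*% t(W2) + rep(b2, each = n)                 # n x K
    S <- S - apply(S, 1, max)
    P <- exp(S); P <- P / rowSums(P)
    loss[e] <- -mean(log(pmax(P[cbind(seq_len(n), as.integer(y))], 1e-12)))
    dS <- (P - Y) / n                                     # n x K
    gW2 <- t(dS) %*% A1; gb2 <- colSums(dS)
    dA1 <- dS %*% W2                                      # n x h
    dZ1 <- dA1 * (1 - A1^2)                               # tansig derivative
    gW1 <- t(dZ1) %*% Xs; gb1 <- colSums(dZ1)
    W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
    W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, center = ctr, scale = scl,
       levels = levels(y), loss = loss)
}

predict_bpnn <- function(fit, X) {
  Xs <- scale(X, fit$center, fit$scale)
  A1 <- tansig(Xs %*% t(fit$W1) + rep(fit$b1, each = nrow(X)))
  S <- A1 %*% t(fit$W2) + rep(fit$b2, each = nrow(X))
  fit$levels[max.col(S, ties.method = "first")]
}

# ---- RBFNN (Gaussian radial-basis-function network) ------------------------
# Centres from k-means on the features; unit activation
# exp(-||x - c||^2 / d^2) with d the median pairwise centre distance by
# default; linear output weights by (ridge-stabilised) least squares.

fit_rbfnn <- function(X, y, hp) {
  set.seed(hp$seed)
  M <- min(as.integer(hp$n_centers), nrow(unique(X)))
  centers <- if (M == 1L) matrix(colMeans(X), 1) else
    suppressWarnings(kmeans(X, centers = M, nstart = 3,
                            iter.max = 50))$centers
  d <- hp$d
  if (is.null(d)) {
    if (nrow(centers) > 1L) {
      d <- stats::median(stats::dist(centers))
      if (d == 0) d <- 1
    } else d <- 1
  }
  Phi <- rbf_design(X, centers, d)
  K <- nlevels(y)
  Y <- diag(K)[as.integer(y), , drop = FALSE]
  A <- crossprod(Phi) + diag(1e-8, ncol(Phi))
  W <- solve(A, crossprod(Phi, Y))                        # M x K
  list(centers = centers, d = d, W = W, levels = levels(y))
}

# design matrix of Gaussian units: exp(-||x - c||^2 / d^2)
rbf_design <- function(X, centers, d) {
  x2 <- rowSums(X^2); c2 <- rowSums(centers^2)
  d2 <- outer(x2, c2, "+") - 2 * X %*% t(centers)
  exp(-pmax(d2, 0) / d^2)
}

predict_rbfnn <- function(fit, X) {
  S <- rbf_design(X, fit$centers, fit$d) %*% fit$W
  fit$levels[max.col(S, ties.method = "first")]
}
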