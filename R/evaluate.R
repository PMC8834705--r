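#' Classification accuracy (percent)
#'
#' `100 * correctly classified / overall sample size`.
#'
#' @param truth,predicted equal-length label vectors.
#' @return Percentage in `[0, 100]`.
#' @export
accuracy <- function(truth, predicted) {
  if (!length(truth)) stop("empty label vectors")
  if (length(truth) != length(predicted)) stop("label lengths differ")
  100 * sum(as.character(truth) == as.character(predicted)) / length(truth)
}

#' Cross-validation configuration
#'
#' @param n_folds number of folds (default 10).
#' @param stratified stratify folds by class (default TRUE; the small
#'   per-grade counts make unstratified folds degenerate).
#' @param seed seed for the fold shuffling.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10L, stratified = TRUE, seed = 1L) {
  if (n_folds < 2L) stop("n_folds must be at least 2")
  structure(list(n_folds = as.integer(n_folds), stratified = stratified,
                 seed = as.integer(seed)),
            class = "cv_config")
}

# seeded fold assignment; stratified folds cycle within each class
make_folds <- function(y, cv) {
  n <- length(y)
  if (cv$n_folds > n) stop("more folds than samples")
  set.seed(cv$seed)
  folds <- integer(n)
  if (cv$stratified) {
    for (lv in levels(factor(y))) {
      idx <- which(y == lv)
      if (length(idx) < 2L)
        stop("class '", lv, "' has fewer than 2 members; it cannot be both ",
             "trained on and tested — merge grades or drop the class")
      # classes smaller than n_folds are spread one-per-fold over a random
      # fold subset; the remaining folds simply test without that class
      if (length(idx) >= cv$n_folds)
        folds[idx] <- sample(rep_len(seq_len(cv$n_folds), length(idx)))
      else
        folds[idx] <- sample(seq_len(cv$n_folds), length(idx))
    }
  } else {
    folds <- sample(rep_len(seq_len(cv$n_folds), n))
  }
  folds
}

#' Cross-validated evaluation of a classifier
#'
#' Stratified, seeded fold assignment; every sample is tested exactly once;
#' the pooled accuracy applies the accuracy formula to the concatenated
#' out-of-fold predictions.
#'
#' @param fit_fun function(X_train, y_train) returning a fitted model.
#' @param predict_fun function(model, X_test) returning labels.
#' @param X feature matrix, or a list of sequences (sequence models).
#' @param y labels.
#' @param cv a [cv_config()].
#' @return A list of class `cv_result`: `fold_accuracy`, `accuracy`,
#'   `confusion` (truth in rows), `predictions`, `folds`.
#' @export
cross_validate <- function(fit_fun, predict_fun, X, y, cv = cv_config()) {
  y <- factor(y)
  is_seq <- is.list(X) && !is.data.frame(X)
  n <- if (is_seq) length(X) else nrow(X)
  if (n != length(y)) stop("X and y lengths differ")
  folds <- make_folds(y, cv)
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  fold_acc <- numeric(cv$n_folds)
  take <- function(obj, idx) if (is_seq) obj[idx] else obj[idx, , drop = FALSE]
  for (f in seq_len(cv$n_folds)) {
    te <- which(folds == f); tr <- which(folds != f)
    model <- fit_fun(take(X, tr), droplevels(y[tr]))
    p <- predict_fun(model, take(X, te))
    pred[te] <- factor(as.character(p), levels = levels(y))
    fold_acc[f] <- accuracy(y[te], pred[te])
  }
  structure(list(fold_accuracy = fold_acc,
                 accuracy = accuracy(y, pred),
                 confusion = table(truth = y, predicted = pred),
                 predictions = pred, folds = folds),
            class = "cv_result")
}

#' Kendall rank correlation (tau-b) between two raters
#'
#' Tie-corrected Kendall correlation for ordinal grades (fail < pass <
#' good).  Errors when either rater's grades are constant (tau undefined).
#'
#' @param rater_a,rater_b equal-length ordinal vectors: numeric codes or
#'   factors/characters on the fail/pass/good scale.
#' @return Kendall tau-b in `[-1, 1]`.
#' @export
kendall_tau <- function(rater_a, rater_b) {
  code <- function(v) {
    if (is.numeric(v)) return(v)
    ord <- c(fail = 0, pass = 1, good = 2)
    v <- tolower(as.character(v))
    if (!all(v %in% names(ord)))
      stop("ordinal grades must be fail/pass/good or numeric")
    unname(ord[v])
  }
  a <- code(rater_a); b <- code(rater_b)
  if (length(a) != length(b)) stop("rater vectors differ in length")
  if (length(unique(a)) < 2L || length(unique(b)) < 2L)
    stop("tau is undefined for constant gradings")
  unname(stats::cor(a, b, method = "kendall"))
}

#' Chi-square comparison of methods' correct/incorrect counts
#'
#' Pearson and likelihood-ratio statistics on a methods x (correct,
#' incorrect) contingency table with expected counts
#' `E = row_total * col_total / grand_total` (no continuity correction);
#' `0 * log(0)` terms are dropped.  Also reports the degrees of freedom, the
#' minimum expected count and how many cells fall below 5 (the usual
#' validity caveat).
#'
#' @param counts integer matrix with at least two rows (methods) and two
#'   columns (correct, incorrect).
#' @return A list of class `chi_square_result`.
#' @export
chi_square_correct_incorrect <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least a 2 x 2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  rt <- rowSums(counts); ct <- colSums(counts); gt <- sum(counts)
  if (any(rt == 0) || any(ct == 0)) stop("zero marginal total")
  expected <- outer(rt, ct) / gt
  pearson <- sum((counts - expected)^2 / expected)
  lr_terms <- counts * log(ifelse(counts > 0, counts / expected, 1))
  likelihood_ratio <- 2 * sum(lr_terms)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  structure(list(pearson = pearson, likelihood_ratio = likelihood_ratio,
                 df = df, expected = expected,
                 p_pearson = stats::pchisq(pearson, df, lower.tail = FALSE),
                 p_likelihood_ratio = stats::pchisq(likelihood_ratio, df,
                                                    lower.tail = FALSE),
                 n_cells_lt5 = sum(expected < 5),
                 min_expected = min(expected)),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat("Pearson chi-square = ", round(x$pearson, 3), ", df = ", x$df,
      ", p = ", signif(x$p_pearson, 3), "\n",
      "Likelihood ratio   = ", round(x$likelihood_ratio, 3),
      ", p = ", signif(x$p_likelihood_ratio, 3), "\n",
      x$n_cells_lt5, " of ", length(x$expected),
      " cells have expected count < 5 (min ", round(x$min_expected, 2),
      ")\n", sep = "")
  invisible(x)
}
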