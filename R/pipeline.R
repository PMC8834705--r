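# End-to-end orchestration: keyframe-compress motions, build DTW features or
# symbol/keyframe sequences, and run cross-validated assessment (grade
# classification within a class) or recognition (which of the classes a
# motion is).

#' Keyframe-compress a motion to its quaternion sequence
#'
#' Forward kinematics, keyframe extraction at the configured rate on the pose
#' coordinates, then the canonicalised quaternion frames at the selected
#' keyframe indices.
#'
#' @param motion a [motion_sequence()].
#' @param kf_config a [compression_config()].
#' @return A `quaternion_sequence` restricted to the keyframes.
#' @export
compress_motion <- function(motion, kf_config = compression_config()) {
  pos <- forward_kinematics(motion)
  kf <- extract_keyframes(pos, kf_config)
  q <- unclass(motion_quaternions(motion))
  structure(q[kf$indices, , , drop = FALSE], class = "quaternion_sequence")
}

# Stream the cohort defined by a generator config: compress each motion as it
# is generated and keep only the compressed quaternion sequences + labels.
# Identical to compressing generate_cohort() output (same substreams).
stream_compressed_cohort <- function(config, kf_config, progress = FALSE) {
  seqs <- list(); rows <- list()
  refs <- vector("list", config$n_classes)
  for (cl in seq_len(config$n_classes)) {
    template <- make_teacher_template(cl, config)
    refs[[cl]] <- vector("list", 3L)
    for (r in 1:3) {
      lm <- teacher_repetition(template, r, config)
      refs[[cl]][[r]] <- compress_motion(lm$motion, kf_config)
    }
    for (st in seq_len(config$n_students)) {
      grade <- draw_grade(config, cl, st)
      lm <- make_student_motion(template, grade, config, subject = st)
      seqs[[length(seqs) + 1L]] <- compress_motion(lm$motion, kf_config)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = lm$subject_id, class_id = cl, grade = grade)
    }
    if (progress) message("compressed class ", cl)
  }
  list(student_seqs = seqs, labels = do.call(rbind, rows),
       teacher_refs = refs)
}

# same streaming compression for an in-memory cohort from generate_cohort()
compress_cohort_motions <- function(cohort, kf_config) {
  refs <- list(); seqs <- list(); rows <- list()
  for (i in seq_along(cohort$motions)) {
    lm <- cohort$motions[[i]]
    cq <- compress_motion(lm$motion, kf_config)
    if (identical(lm$role, "teacher")) {
      cl <- as.character(lm$class_id)
      if (is.null(refs[[cl]])) refs[[cl]] <- list()
      refs[[cl]][[length(refs[[cl]]) + 1L]] <- cq
    } else {
      seqs[[length(seqs) + 1L]] <- cq
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = lm$subject_id, class_id = lm$class_id, grade = lm$grade)
    }
  }
  refs <- refs[order(as.integer(names(refs)))]
  names(refs) <- NULL
  list(student_seqs = seqs, labels = do.call(rbind, rows),
       teacher_refs = refs)
}

#' Method specification for the evaluation pipeline
#'
#' @param family `"dtw"` (DTW distance features + a feature classifier),
#'   `"hmm"` (per-class discrete HMMs on vector-quantised keyframe
#'   sequences) or `"rnn"` (recurrent network on keyframe quaternion
#'   frames).
#' @param classifier for `family = "dtw"`: a [classifier_spec()].
#' @param ... family hyperparameters: HMM `n_states` (5), `codebook_size`
#'   (16), `max_iter` (30); RNN `kind` ("lstm"/"bilstm"/"gru"),
#'   `hidden_dim` (32), `epochs` (200), `learning_rate` (0.01).
#' @param seed integer seed for the stochastic trainers.
#' @return A list of class `method_spec`.
#' @export
method_spec <- function(family = c("dtw", "hmm", "rnn"),
                        classifier = classifier_spec("knn"), seed = 1L,
                        ...) {
  family <- match.arg(family)
  opts <- list(...)
  if (family == "dtw" && !inherits(classifier, "classifier_spec"))
    stop("dtw family needs a classifier_spec")
  structure(list(family = family, classifier = classifier,
                 seed = as.integer(seed), options = opts),
            class = "method_spec")
}

seq_method_fitter <- function(method) {
  o <- method$options
  if (method$family == "hmm") {
    n_states <- o$n_states %||% 5L
    M <- o$codebook_size %||% 16L
    max_iter <- o$max_iter %||% 30L
    list(
      fit = function(seqs, y) {
        cb <- fit_codebook(seqs, M = M, seed = method$seed)
        models <- lapply(levels(y), function(lv) {
          obs <- lapply(seqs[y == lv], quantize, codebook = cb)
          hmm_fit(obs, N = n_states, M = M, seed = method$seed,
                  max_iter = max_iter)
        })
        names(models) <- levels(y)
        list(codebook = cb, models = models)
      },
      predict = function(model, seqs) {
        vapply(seqs, function(s)
          hmm_classify(model$models, quantize(s, model$codebook)),
          character(1))
      })
  } else {
    kind <- o$kind %||% "lstm"
    list(
      fit = function(seqs, y) {
        rnn_fit(kind, lapply(seqs, flatten_quaternions), y,
                hidden_dim = o$hidden_dim %||% 32L,
                epochs = o$epochs %||% 200L,
                learning_rate = o$learning_rate %||% 0.01,
                seed = method$seed)
      },
      predict = function(model, seqs) {
        as.character(predict(model, lapply(seqs, flatten_quaternions)))
      })
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full assessment or recognition workflow
#'
#' Builds features or sequences from the compressed cohort and
#' cross-validates the chosen method.  `task = "recognize"` classifies which
#' motion class each student performed (features: DTW distance to each
#' class's averaged teacher reference).  `task = "assess"` grades students
#' against their own class's teacher (features: per-joint DTW distances
#' averaged over the teacher repetitions), one model per class, and reports
#' per-class accuracies plus their pooled mean.
#'
#' @param cohort a [generator_config()] (motions are then generated and
#'   compressed on the fly, which keeps memory flat) or the result of
#'   [generate_cohort()].
#' @param method a [method_spec()].
#' @param task `"recognize"` or `"assess"`.
#' @param cv a [cv_config()].
#' @param kf_config a [compression_config()]; compression rate 15% by
#'   default.
#' @param dtw_cfg a [dtw_config()].
#' @param progress emit per-class progress messages.
#' @return A list of class `eval_report`.
#' @export
assess_pipeline <- function(cohort, method = method_spec("dtw"),
                            task = c("recognize", "assess"),
                            cv = cv_config(),
                            kf_config = compression_config(),
                            dtw_cfg = dtw_config(), progress = FALSE) {
  task <- match.arg(task)
  stopifnot(inherits(method, "method_spec"))
  data <- if (inherits(cohort, "generator_config"))
    stream_compressed_cohort(cohort, kf_config, progress = progress)
  else if (is.list(cohort) && !is.null(cohort$motions))
    compress_cohort_motions(cohort, kf_config)
  else stop("cohort must be a generator_config or a generate_cohort() result")

  labels <- data$labels
  if (task == "assess" && length(unique(labels$grade)) < 2L)
    stop("assessment needs at least two distinct grades in the cohort")

  if (method$family == "dtw") {
    fit_fun <- function(X, y) train_classifier(method$classifier, X, y)
    predict_fun <- function(m, X) predict(m, X)
  } else {
    sm <- seq_method_fitter(method)
    fit_fun <- sm$fit; predict_fun <- sm$predict
  }

  if (task == "recognize") {
    inputs <- if (method$family == "dtw") {
      lib <- lapply(data$teacher_refs, average_reference)
      t(vapply(data$student_seqs, build_recognition_features,
               numeric(length(lib)), teacher_library = lib,
               config = dtw_cfg))
    } else data$student_seqs
    res <- cross_validate(fit_fun, predict_fun, inputs,
                          factor(labels$class_id), cv)
    report <- list(task = task, method = method, accuracy = res$accuracy,
                   fold_accuracy = res$fold_accuracy,
                   confusion = res$confusion, n = nrow(labels))
  } else {
    per_class <- list()
    all_truth <- character(0); all_pred <- character(0)
    for (cl in sort(unique(labels$class_id))) {
      idx <- which(labels$class_id == cl)
      y <- factor(labels$grade[idx], levels = c("good", "pass", "fail"))
      y <- droplevels(y)
      # grades too rare to cross-validate within this class are set aside
      rare <- names(which(table(y) < 2L))
      if (length(rare)) {
        warning("class ", cl, ": grade(s) ", paste(rare, collapse = ", "),
                " have fewer than 2 members and are excluded")
        keep <- !(as.character(y) %in% rare)
        idx <- idx[keep]; y <- droplevels(y[keep])
      }
      if (nlevels(y) < 2L) {
        warning("class ", cl, " has a single grade level; skipped")
        next
      }
      inputs <- if (method$family == "dtw") {
        t(vapply(data$student_seqs[idx], build_assessment_features,
                 numeric(dim(unclass(data$student_seqs[[1]]))[2]),
                 teacher_refs = data$teacher_refs[[cl]], config = dtw_cfg))
      } else data$student_seqs[idx]
      res <- cross_validate(fit_fun, predict_fun, inputs, y, cv)
      per_class[[as.character(cl)]] <- list(accuracy = res$accuracy,
                                            confusion = res$confusion)
      all_truth <- c(all_truth, as.character(y))
      all_pred <- c(all_pred, as.character(res$predictions))
      if (progress) message("assessed class ", cl)
    }
    report <- list(task = task, method = method,
                   per_class_accuracy = vapply(per_class, `[[`, numeric(1),
                                               "accuracy"),
                   accuracy = accuracy(all_truth, all_pred),
                   confusion = table(truth = all_truth,
                                     predicted = all_pred),
                   n = length(all_truth))
  }
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> task = ", x$task, ", family = ", x$method$family,
      ", n = ", x$n, "\n", sep = "")
  if (!is.null(x$per_class_accuracy)) {
    cat("per-class accuracy (%):\n")
    print(round(x$per_class_accuracy, 2))
  }
  cat("pooled accuracy: ", round(x$accuracy, 2), "%\n", sep = "")
  invisible(x)
}
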