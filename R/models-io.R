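# Versioned JSON container for trained models.  Hand-authored models (knn,
# bpnn, rbfnn, hmm, rnn) serialise their numeric arrays directly; models
# backed by external fitters store a base64-encoded R serialisation.

MODEL_FORMAT_VERSION <- 1L

#' Save a trained model to a JSON container
#'
#' @param model a `trained_classifier`, `hmm_model` or `rnn_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  kind <- if (inherits(model, "hmm_model")) "hmm"
          else if (inherits(model, "rnn_model")) "rnn"
          else if (inherits(model, "trained_classifier")) model$spec$kind
          else stop("unsupported model type")
  payload <- list(format_version = MODEL_FORMAT_VERSION, kind = kind)
  if (inherits(model, "hmm_model")) {
    payload$model <- list(pi = model$pi, A = model$A, B = model$B)
  } else if (inherits(model, "rnn_model")) {
    payload$model <- unclass(model)
  } else if (kind %in% c("knn", "bpnn", "rbfnn")) {
    payload$model <- list(spec = unclass(model$spec), fit = model$fit,
                          classes = model$classes,
                          n_features = model$n_features)
  } else {
    payload$spec <- unclass(model$spec)
    payload$classes <- model$classes
    payload$n_features <- model$n_features
    payload$serialized <- jsonlite::base64_enc(serialize(model$fit, NULL))
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON file path.
#' @return The reconstructed model object.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(payload$format_version), MODEL_FORMAT_VERSION))
    stop("unsupported model format version")
  kind <- payload$kind
  restore_matrix <- function(x) if (is.data.frame(x)) as.matrix(x) else x
  if (kind == "hmm") {
    return(hmm_model(payload$model$pi, restore_matrix(payload$model$A),
                     restore_matrix(payload$model$B)))
  }
  if (kind == "rnn") {
    m <- payload$model
    m$params <- rapply(m$params, restore_matrix, how = "replace")
    m$loss_trace <- as.numeric(m$loss_trace)
    return(structure(m, class = "rnn_model"))
  }
  if (kind %in% c("knn", "bpnn", "rbfnn")) {
    m <- payload$model
    fit <- rapply(m$fit, restore_matrix, how = "replace")
    if (kind == "knn") {
      fit$X <- as.matrix(fit$X)
      fit$y <- factor(fit$y, levels = m$classes)
      fit$k <- as.integer(fit$k)
    }
    spec <- structure(m$spec, class = "classifier_spec")
    return(structure(list(spec = spec, fit = fit, classes = m$classes,
                          n_features = as.integer(m$n_features)),
                     class = "trained_classifier"))
  }
  fit <- unserialize(jsonlite::base64_dec(payload$serialized))
  spec <- structure(payload$spec, class = "classifier_spec")
  structure(list(spec = spec, fit = fit, classes = payload$classes,
                 n_features = as.integer(payload$n_features)),
            class = "trained_classifier")
}
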