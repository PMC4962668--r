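# Versioned JSON serialization for trained models: sparse weight entries for
# the NER and relation models, the correlation matrix in triplet form for
# the SSI model. Embedding models use the word2vec text format (see
# write_word2vec()/read_word2vec()).

.MODEL_VERSION <- "1"

#' Save a trained model as JSON
#'
#' @param model an `ner_model`, `ssi_model` or `relation_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  obj <- if (inherits(model, "ner_model")) {
    list(version = .MODEL_VERSION, class = "ner_model",
         weights = as.list(model$weights),
         averaged_weights = as.list(model$averaged_weights),
         feature_config = model$feature_config)
  } else if (inherits(model, "ssi_model")) {
    W <- model$correlation
    nz <- which(W != 0, arr.ind = TRUE)
    list(version = .MODEL_VERSION, class = "ssi_model", vocab = model$vocab,
         i = unname(nz[, 1]), j = unname(nz[, 2]), x = unname(W[nz]),
         margin = model$margin, learning_rate = model$learning_rate,
         epochs = model$epochs, seed = model$seed)
  } else if (inherits(model, "relation_model")) {
    list(version = .MODEL_VERSION, class = "relation_model",
         weights = as.list(model$weights), bias = model$bias,
         feature_names = model$feature_names, C = model$C)
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON file path.
#' @return the model object.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$version, .MODEL_VERSION)) {
    stop("unsupported model file version: ", obj$version)
  }
  numvec <- function(x) stats::setNames(vapply(x, as.numeric, numeric(1)), names(x))
  switch(obj$class,
    ner_model = structure(list(
      weights = numvec(obj$weights),
      averaged_weights = numvec(obj$averaged_weights),
      feature_config = obj$feature_config), class = "ner_model"),
    ssi_model = {
      vocab <- unlist(obj$vocab)
      W <- matrix(0, length(vocab), length(vocab), dimnames = list(vocab, vocab))
      W[cbind(unlist(obj$i), unlist(obj$j))] <- unlist(obj$x)
      structure(list(correlation = W, vocab = vocab, margin = obj$margin,
                     learning_rate = obj$learning_rate, epochs = obj$epochs,
                     seed = obj$seed), class = "ssi_model")
    },
    relation_model = structure(list(
      weights = numvec(obj$weights), bias = obj$bias,
      feature_names = unlist(obj$feature_names), C = obj$C),
      class = "relation_model"),
    stop("unsupported model class in file: ", obj$class))
}
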