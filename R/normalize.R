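# Concept normalization: a supervised semantic indexing (SSI) model scoring
# mention/concept pairs via a bilinear token-correlation matrix, a
# negative-sampling skip-gram embedding model, and the sequential back-off
# combining them (SSI first, embeddings for pairs SSI leaves unlinked).

.bow_tokens <- function(text) {
  w <- sc_words(tolower(text))
  w[grepl("[[:alnum:]]", w)]
}

concept_name_tokens <- function(ontology, id) {
  unlist(lapply(ontology$synonyms[[id]], .bow_tokens), use.names = FALSE)
}

# bag-of-words count vector over the model vocabulary
.bow_vec <- function(tokens, vocab) {
  v <- numeric(length(vocab))
  idx <- match(tokens, vocab)
  idx <- idx[!is.na(idx)]
  if (length(idx)) {
    t <- table(idx)
    v[as.integer(names(t))] <- as.numeric(t)
  }
  v
}

#' Train the SSI token-correlation model
#'
#' Learns a correlation matrix `W` between tokens of the training mentions
#' and tokens of the ontology names; `score(m, c) = bow(m)' W bow(c)`.
#' `W` is initialized to the identity (so the untrained score is the
#' token-overlap count) and updated by margin ranking: for each mention with
#' a linked gold concept, a same-branch negative concept is sampled and, if
#' the gold does not beat it by `margin`, a rank-one update is applied.
#'
#' @param corpus list of `cid_document` with gold, linked mentions.
#' @param ontology a `cid_ontology`.
#' @param margin ranking margin.
#' @param learning_rate update step size.
#' @param epochs passes over the mentions.
#' @param seed integer seed (negative sampling and shuffling).
#' @return an object of class `ssi_model` with fields `correlation`
#'   (dense matrix with token dimnames) and `vocab`.
#' @export
train_ssi <- function(corpus, ontology, margin = 1, learning_rate = 0.01,
                      epochs = 5L, seed = 1L) {
  mention_texts <- character(); mention_ids <- character()
  for (doc in corpus) {
    m <- doc$mentions
    keep <- m$provenance == "gold" & m$concept_id != UNLINKED
    mention_texts <- c(mention_texts, m$text[keep])
    mention_ids <- c(mention_ids, m$concept_id[keep])
  }
  vocab <- sort(unique(c(
    unlist(lapply(mention_texts, .bow_tokens), use.names = FALSE),
    unlist(lapply(ontology$concepts$id, function(id)
      concept_name_tokens(ontology, id)), use.names = FALSE))))
  W <- diag(1, length(vocab))
  dimnames(W) <- list(vocab, vocab)
  model <- structure(list(correlation = W, vocab = vocab, margin = margin,
                          learning_rate = learning_rate, epochs = epochs,
                          seed = seed),
                     class = "ssi_model")
  if (epochs == 0L || !length(mention_texts)) return(model)

  cvecs <- lapply(ontology$concepts$id, function(id)
    .bow_vec(concept_name_tokens(ontology, id), vocab))
  names(cvecs) <- ontology$concepts$id
  mvecs <- lapply(mention_texts, function(tx) .bow_vec(.bow_tokens(tx), vocab))

  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(mention_texts))
    for (ix in ord) {
      gold <- mention_ids[ix]
      br <- concept_branch(ontology, gold)
      if (is.na(br)) next
      negs <- setdiff(branch_concepts(ontology, br), gold)
      if (!length(negs)) next
      neg <- negs[sample.int(length(negs), 1L)]
      bm <- mvecs[[ix]]
      sp <- as.numeric(bm %*% W %*% cvecs[[gold]])
      sn <- as.numeric(bm %*% W %*% cvecs[[neg]])
      if (sp < sn + margin) {
        W <- W + learning_rate * outer(bm, cvecs[[gold]] - cvecs[[neg]])
      }
    }
  }
  model$correlation <- W
  model
}

#' SSI score of a mention text against a concept
#'
#' @param model an `ssi_model`.
#' @param mention_text surface string.
#' @param ontology a `cid_ontology`.
#' @param concept_id concept to score against.
#' @return numeric score (`bow(m)' W bow(c)`; tokens outside the model
#'   vocabulary contribute 0).
#' @export
ssi_score <- function(model, mention_text, ontology, concept_id) {
  bm <- .bow_vec(.bow_tokens(mention_text), model$vocab)
  bc <- .bow_vec(concept_name_tokens(ontology, concept_id), model$vocab)
  as.numeric(bm %*% model$correlation %*% bc)
}

#' @export
print.ssi_model <- function(x, ...) {
  cat(sprintf("<ssi_model: %d-token vocabulary>\n", length(x$vocab)))
  invisible(x)
}

#' Train skip-gram word embeddings with negative sampling
#'
#' A small stochastic-gradient trainer for the skip-gram objective with
#' negative sampling; meant for desk-scale corpora. A pretrained model in
#' word2vec text format can be used instead via [read_word2vec()].
#'
#' @param sentences list of character vectors (tokens; matched lowercased).
#' @param dim embedding dimension (default 200).
#' @param window symmetric context window size.
#' @param negatives negative samples per positive pair.
#' @param epochs passes over the corpus.
#' @param learning_rate initial step size.
#' @param seed integer seed.
#' @return an object of class `embedding_model` with a `vectors` matrix
#'   (rows = vocabulary tokens).
#' @export
train_skipgram <- function(sentences, dim = 200L, window = 2L, negatives = 5L,
                           epochs = 5L, learning_rate = 0.05, seed = 1L) {
  stopifnot(length(sentences) > 0L)
  toks <- lapply(sentences, tolower)
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  V <- length(vocab)
  set.seed(seed)
  inp <- matrix(stats::runif(V * dim, -0.5, 0.5) / dim, V, dim,
                dimnames = list(vocab, NULL))
  out <- matrix(0, V, dim, dimnames = list(vocab, NULL))
  freq <- table(factor(unlist(toks, use.names = FALSE), levels = vocab))
  neg_prob <- as.numeric(freq)^0.75
  neg_prob <- neg_prob / sum(neg_prob)
  sigm <- function(z) 1 / (1 + exp(-z))
  for (ep in seq_len(epochs)) {
    lr <- learning_rate * (1 - (ep - 1) / epochs)
    for (s in toks) {
      ids <- match(s, vocab)
      n <- length(ids)
      for (c in seq_len(n)) {
        lo <- max(1L, c - window); hi <- min(n, c + window)
        for (j in lo:hi) {
          if (j == c) next
          ci <- ids[c]; oj <- ids[j]
          vin <- inp[ci, ]
          grad_in <- numeric(dim)
          # positive pair
          g <- (1 - sigm(sum(vin * out[oj, ]))) * lr
          grad_in <- grad_in + g * out[oj, ]
          out[oj, ] <- out[oj, ] + g * vin
          # negatives
          negs <- sample.int(V, negatives, replace = TRUE, prob = neg_prob)
          for (nk in negs) {
            if (nk == oj) next
            g <- -sigm(sum(vin * out[nk, ])) * lr
            grad_in <- grad_in + g * out[nk, ]
            out[nk, ] <- out[nk, ] + g * vin
          }
          inp[ci, ] <- vin + grad_in
        }
      }
    }
  }
  structure(list(vectors = inp, dim = dim, window = window,
                 negatives = negatives, epochs = epochs, seed = seed),
            class = "embedding_model")
}

#' Read embeddings in word2vec text format
#'
#' First line `vocab_size dim`, then one token and its vector per line.
#'
#' @param x path or character vector of lines.
#' @return an `embedding_model`.
#' @export
read_word2vec <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  hdr <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
  body <- strsplit(trimws(lines[-1]), "[[:space:]]+")
  toks <- vapply(body, `[[`, character(1), 1L)
  vecs <- t(vapply(body, function(f) as.numeric(f[-1]), numeric(hdr[2])))
  rownames(vecs) <- toks
  structure(list(vectors = vecs, dim = hdr[2], window = NA_integer_,
                 negatives = NA_integer_, epochs = NA_integer_,
                 seed = NA_integer_),
            class = "embedding_model")
}

#' Write embeddings in word2vec text format
#' @param emb an `embedding_model`.
#' @param path optional output path.
#' @return character lines (invisibly when `path` given).
#' @export
write_word2vec <- function(emb, path = NULL) {
  v <- emb$vectors
  out <- c(paste(nrow(v), ncol(v)),
           vapply(seq_len(nrow(v)), function(i)
             paste(rownames(v)[i], paste(format(v[i, ], digits = 8L),
                                         collapse = " ")), character(1)))
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}

.avg_vec <- function(tokens, emb) {
  idx <- match(tokens, rownames(emb$vectors))
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(NULL)
  colMeans(emb$vectors[idx, , drop = FALSE])
}

#' Cosine similarity between a mention and a concept's preferred name
#'
#' Both sides are represented by the average of their in-vocabulary token
#' vectors; out-of-vocabulary tokens are ignored and a fully
#' out-of-vocabulary side yields 0.
#'
#' @param mention_text surface string.
#' @param ontology a `cid_ontology`.
#' @param concept_id concept id.
#' @param emb an `embedding_model`.
#' @return cosine similarity in `[-1, 1]` (0 when undefined).
#' @export
embedding_similarity <- function(mention_text, ontology, concept_id, emb) {
  a <- .avg_vec(.bow_tokens(mention_text), emb)
  pref <- ontology$concepts$preferred_name[match(concept_id, ontology$concepts$id)]
  b <- .avg_vec(.bow_tokens(pref), emb)
  if (is.null(a) || is.null(b)) return(0)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Two-stage back-off normalization of a mention
#'
#' Candidates are the concepts of the branch matching the mention type
#' (C for diseases, D for chemicals). They are ranked by SSI score; if the
#' top score reaches `ssi_threshold` it wins. Otherwise candidates are
#' re-ranked by embedding similarity with threshold `emb_threshold`.
#' If both stages fail the mention is left unlinked (`NONE`).
#'
#' @param mention_text surface string.
#' @param type `"Chemical"` or `"Disease"`.
#' @param ontology a `cid_ontology`.
#' @param ssi an `ssi_model` (or `NULL` to skip the stage).
#' @param emb an `embedding_model` (or `NULL` to skip the stage).
#' @param ssi_threshold,emb_threshold acceptance thresholds (default 0).
#' @param none_threshold score reported for the NONE outcome.
#' @return list with `concept_id` (id or `NA` for NONE), `score`, and
#'   `stage` (`"ssi"`, `"embedding"` or `"none"`).
#' @export
normalize_backoff <- function(mention_text, type, ontology, ssi = NULL,
                              emb = NULL, ssi_threshold = 0, emb_threshold = 0,
                              none_threshold = 0) {
  branch <- if (type == "Disease") "C" else "D"
  cands <- branch_concepts(ontology, branch)
  if (!length(cands)) {
    return(list(concept_id = NA_character_, score = none_threshold, stage = "none"))
  }
  cands <- sort(cands)
  if (!is.null(ssi)) {
    sc <- vapply(cands, function(id) ssi_score(ssi, mention_text, ontology, id),
                 numeric(1))
    top <- which.max(sc)
    if (sc[top] >= ssi_threshold) {
      return(list(concept_id = cands[top], score = sc[top], stage = "ssi"))
    }
  }
  if (!is.null(emb)) {
    sc <- vapply(cands, function(id)
      embedding_similarity(mention_text, ontology, id, emb), numeric(1))
    top <- which.max(sc)
    if (sc[top] >= emb_threshold) {
      return(list(concept_id = cands[top], score = sc[top], stage = "embedding"))
    }
  }
  list(concept_id = NA_character_, score = none_threshold, stage = "none")
}
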