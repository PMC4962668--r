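# Structured-perceptron named entity recognition over the five-tag alphabet
# {B-DS, I-DS, B-CD, I-CD, O} (DS = disease, CD = chemical), decoded by
# left-to-right beam search. Training uses inexact search with early-update
# violation fixing and weight averaging.

NER_TAGS <- c("O", "B-CD", "B-DS", "I-CD", "I-DS")

# single-character sort keys implementing the deterministic tie-break
# preference O < B-CD < B-DS < I-CD < I-DS
.TAG_KEY <- c("O" = "a", "B-CD" = "b", "B-DS" = "c", "I-CD" = "d", "I-DS" = "e")

bio_valid_next <- function(prev, tag) {
  if (tag == "I-CD") return(prev %in% c("B-CD", "I-CD"))
  if (tag == "I-DS") return(prev %in% c("B-DS", "I-DS"))
  TRUE
}

.token_shape <- function(w, i) {
  f <- character()
  if (grepl("^[A-Z]", w)) f <- c(f, "sh:init-cap")
  if (grepl("^[A-Z]+$", w) && nchar(w) > 1L) f <- c(f, "sh:all-caps")
  if (grepl("[0-9]", w)) f <- c(f, "sh:has-digit")
  if (grepl("^[0-9]+$", w)) f <- c(f, "sh:all-digit")
  if (grepl("-", w, fixed = TRUE)) f <- c(f, "sh:has-hyphen")
  if (i == 1L) f <- c(f, "sh:first-tok")
  f
}

# longest ontology synonym match covering token i (window capped at 6 tokens)
.dict_flags <- function(sentence, i, ontology) {
  if (is.null(ontology)) return(character())
  toks <- tolower(sentence$tokens$text)
  n <- length(toks)
  best_len <- 0L; best_ids <- character(); best_a <- NA_integer_
  for (a in max(1L, i - 5L):i) {
    for (b in i:min(n, a + 5L)) {
      len <- b - a + 1L
      if (len <= best_len) next
      ids <- ontology_lookup(ontology, paste(toks[a:b], collapse = " "))
      if (length(ids)) { best_len <- len; best_ids <- ids; best_a <- a }
    }
  }
  if (!best_len) return(character())
  branches <- unique(vapply(best_ids, function(id) concept_branch(ontology, id),
                            character(1)))
  f <- paste0("dict:", branches)
  if (!is.na(best_a) && best_a == i) f <- c(f, paste0("dict:", branches, ":B"))
  f
}

#' NER feature extraction for one token position
#'
#' Emits the standard lexicographic feature set: word identity and stem,
#' orthographic shape, +/-2 context window, POS of the current and
#' neighboring tokens, dictionary-hit flags per ontology branch, and a
#' previous-tag transition feature. Feature names are namespaced and
#' deterministic; the current tag is conjoined at scoring time.
#'
#' @param sentence a `cid_sentence`.
#' @param i token index (1-based).
#' @param prev previous tag (use `"O"` at the first position).
#' @param ontology optional `cid_ontology` for dictionary features.
#' @param config named logical flags `orthography`, `context`, `pos`,
#'   `dictionary`; missing flags default to `TRUE`.
#' @return character vector of feature names (multiplicity allowed).
#' @export
extract_ner_features <- function(sentence, i, prev = "O", ontology = NULL,
                                 config = NULL) {
  toks <- sentence$tokens
  n <- nrow(toks)
  stopifnot(i >= 1L, i <= n)
  on <- function(flag) is.null(config) || is.null(config[[flag]]) || isTRUE(config[[flag]])
  w <- toks$text[i]
  lw <- tolower(w)
  at <- function(j, col) if (j >= 1L && j <= n) toks[[col]][j] else "<pad>"
  f <- c(paste0("w:", lw), paste0("stem:", toks$stem[i]))
  if (on("orthography")) {
    f <- c(f, .token_shape(w, i),
           paste0("pre3:", substr(lw, 1L, 3L)),
           paste0("suf3:", substring(lw, max(1L, nchar(lw) - 2L))))
  }
  if (on("context")) {
    f <- c(f,
           paste0("w-2:", tolower(at(i - 2L, "text"))),
           paste0("w-1:", tolower(at(i - 1L, "text"))),
           paste0("w+1:", tolower(at(i + 1L, "text"))),
           paste0("w+2:", tolower(at(i + 2L, "text"))),
           paste0("bg:", tolower(at(i - 1L, "text")), "_", lw))
  }
  if (on("pos")) {
    f <- c(f, paste0("p0:", at(i, "pos")),
           paste0("p-1:", at(i - 1L, "pos")),
           paste0("p+1:", at(i + 1L, "pos")),
           paste0("pbg:", at(i - 1L, "pos"), "_", at(i, "pos")))
  }
  if (on("dictionary")) f <- c(f, .dict_flags(sentence, i, ontology))
  c(f, paste0("prev:", prev))
}

.wsum <- function(weights, keys) {
  v <- weights[keys]
  sum(v, na.rm = TRUE)
}

# feature extraction memoized per (position, previous tag); cache is a
# per-sentence environment supplied by the decoding loops
.ner_feats_cached <- function(sentence, i, prev, ontology, config, cache) {
  if (is.null(cache)) {
    return(extract_ner_features(sentence, i, prev, ontology, config))
  }
  key <- paste0(i, "|", prev)
  f <- cache[[key]]
  if (is.null(f)) {
    f <- extract_ner_features(sentence, i, prev, ontology, config)
    cache[[key]] <- f
  }
  f
}

#' Score a full tag sequence under an NER model
#'
#' The same left-to-right scoring function used by [beam_decode()]:
#' `sum_i w . features(x, i, y_{i-1})` conjoined with `y_i`. Exposed so that
#' exhaustive-enumeration checks can score candidate sequences identically.
#'
#' @param sentence a `cid_sentence`.
#' @param model an `ner_model` (see [train_perceptron()]).
#' @param tags character vector of tags, one per token.
#' @param ontology optional ontology for dictionary features.
#' @param use_average score with averaged weights (default) or raw weights.
#' @param cache optional per-sentence environment memoizing feature
#'   extraction (useful when scoring many sequences of one sentence).
#' @return numeric score.
#' @export
score_tag_sequence <- function(sentence, model, tags, ontology = NULL,
                               use_average = TRUE, cache = NULL) {
  w <- if (use_average) model$averaged_weights else model$weights
  s <- 0
  prev <- "O"
  for (i in seq_along(tags)) {
    f <- .ner_feats_cached(sentence, i, prev, ontology, model$feature_config, cache)
    s <- s + .wsum(w, paste0(tags[i], "|", f))
    prev <- tags[i]
  }
  s
}

#' Beam-search decoding of the best BIO-valid tag sequence
#'
#' Ties are broken deterministically: states are ranked by score, then by the
#' lexicographic key of their tag prefix under the order
#' O < B-CD < B-DS < I-CD < I-DS, so a zero-weight model yields all-O.
#'
#' @param sentence a `cid_sentence`.
#' @param model an `ner_model`.
#' @param beam_width positive integer.
#' @param ontology optional ontology for dictionary features.
#' @param use_average decode with averaged weights (default).
#' @return list with elements `tags` (character) and `score` (numeric).
#' @export
beam_decode <- function(sentence, model, beam_width = 5L, ontology = NULL,
                        use_average = TRUE) {
  stopifnot(beam_width >= 1L)
  n <- nrow(sentence$tokens)
  if (n == 0L) return(list(tags = character(), score = 0))
  w <- if (use_average) model$averaged_weights else model$weights
  cache <- new.env(hash = TRUE, parent = emptyenv())
  beam <- list(list(tags = character(), key = "", score = 0))
  for (i in seq_len(n)) {
    cand <- list()
    for (st in beam) {
      prev <- if (i == 1L) "O" else st$tags[i - 1L]
      f <- .ner_feats_cached(sentence, i, prev, ontology, model$feature_config, cache)
      for (tag in NER_TAGS) {
        if (!bio_valid_next(if (i == 1L) "O" else prev, tag)) next
        if (i == 1L && startsWith(tag, "I-")) next
        cand[[length(cand) + 1L]] <- list(
          tags = c(st$tags, tag),
          key = paste0(st$key, .TAG_KEY[[tag]]),
          score = st$score + .wsum(w, paste0(tag, "|", f)))
      }
    }
    sc <- vapply(cand, `[[`, numeric(1), "score")
    ky <- vapply(cand, `[[`, character(1), "key")
    ord <- order(-sc, ky, method = "radix")
    beam <- cand[ord[seq_len(min(beam_width, length(cand)))]]
  }
  list(tags = beam[[1]]$tags, score = beam[[1]]$score)
}

# gold BIO tags for a sentence from the document's typed mentions
gold_tags <- function(doc, k) {
  sent <- doc$sentences[[k]]
  tags <- rep("O", nrow(sent$tokens))
  m <- doc$mentions
  if (!nrow(m)) return(tags)
  for (j in seq_len(nrow(m))) {
    idx <- tokens_in_span(sent, m$start[j], m$end[j])
    if (!length(idx)) next
    code <- if (m$type[j] == "Disease") "DS" else "CD"
    tags[idx[1]] <- paste0("B-", code)
    if (length(idx) > 1L) tags[idx[-1]] <- paste0("I-", code)
  }
  tags
}

# feature keys (tag-conjoined) for a tag prefix, as a character vector
.prefix_keys <- function(sentence, tags, upto, ontology, config, cache = NULL) {
  keys <- character()
  prev <- "O"
  for (j in seq_len(upto)) {
    f <- .ner_feats_cached(sentence, j, prev, ontology, config, cache)
    keys <- c(keys, paste0(tags[j], "|", f))
    prev <- tags[j]
  }
  keys
}

.env_add <- function(env, keys, mult) {
  for (k in keys) {
    cur <- if (is.null(env[[k]])) 0 else env[[k]]
    env[[k]] <- cur + mult
  }
}

#' Train the structured perceptron NER model
#'
#' Online training with beam search and early-update violation fixing: each
#' sentence is decoded left to right; at the first position where the gold
#' prefix falls out of the beam the weights are updated with the feature
#' difference between the gold prefix and the current best prefix, and the
#' sentence is abandoned. A running weight average is maintained and used for
#' decoding.
#'
#' @param corpus list of `cid_document` with gold mentions.
#' @param ontology optional ontology for dictionary features.
#' @param epochs number of passes over the data.
#' @param beam_width beam width used during training.
#' @param seed integer seed controlling instance shuffling.
#' @param feature_config optional named logical flags (see
#'   [extract_ner_features()]).
#' @return an object of class `ner_model` with sparse named-numeric
#'   `weights` and `averaged_weights`.
#' @export
train_perceptron <- function(corpus, ontology = NULL, epochs = 10L,
                             beam_width = 5L, seed = 1L,
                             feature_config = NULL) {
  items <- list()
  for (doc in corpus) {
    for (k in seq_along(doc$sentences)) {
      if (nrow(doc$sentences[[k]]$tokens) == 0L) next
      items[[length(items) + 1L]] <- list(sent = doc$sentences[[k]],
                                          gold = gold_tags(doc, k),
                                          cache = new.env(hash = TRUE,
                                                          parent = emptyenv()))
    }
  }
  wenv <- new.env(hash = TRUE, parent = emptyenv())
  uenv <- new.env(hash = TRUE, parent = emptyenv())
  cnt <- 0L
  snapshot <- function(env) {
    keys <- ls(env, all.names = TRUE)
    stats::setNames(vapply(keys, function(k) env[[k]], numeric(1)), keys)
  }
  model <- structure(list(weights = numeric(), averaged_weights = numeric(),
                          feature_config = feature_config),
                     class = "ner_model")
  if (epochs == 0L || !length(items)) return(model)

  set.seed(seed)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(items))
    for (ix in ord) {
      cnt <- cnt + 1L
      it <- items[[ix]]
      sent <- it$sent; gold <- it$gold
      n <- length(gold)
      cur <- snapshot(wenv)
      # beam with gold tracking
      beam <- list(list(tags = character(), key = "", score = 0))
      gold_key <- ""
      violated <- FALSE
      for (i in seq_len(n)) {
        cand <- list()
        for (st in beam) {
          prev <- if (i == 1L) "O" else st$tags[i - 1L]
          f <- .ner_feats_cached(sent, i, prev, ontology, feature_config, it$cache)
          for (tag in NER_TAGS) {
            if (i == 1L && startsWith(tag, "I-")) next
            if (!bio_valid_next(if (i == 1L) "O" else prev, tag)) next
            cand[[length(cand) + 1L]] <- list(
              tags = c(st$tags, tag),
              key = paste0(st$key, .TAG_KEY[[tag]]),
              score = st$score + .wsum(cur, paste0(tag, "|", f)))
          }
        }
        sc <- vapply(cand, `[[`, numeric(1), "score")
        ky <- vapply(cand, `[[`, character(1), "key")
        ord2 <- order(-sc, ky, method = "radix")
        beam <- cand[ord2[seq_len(min(beam_width, length(cand)))]]
        gold_key <- paste0(gold_key, .TAG_KEY[[gold[i]]])
        if (!any(vapply(beam, `[[`, character(1), "key") == gold_key)) {
          # early update at the first gold-prefix fall-out
          gk <- .prefix_keys(sent, gold, i, ontology, feature_config, it$cache)
          pk <- .prefix_keys(sent, beam[[1]]$tags, i, ontology, feature_config,
                             it$cache)
          .env_add(wenv, gk, 1); .env_add(uenv, gk, cnt)
          .env_add(wenv, pk, -1); .env_add(uenv, pk, -cnt)
          violated <- TRUE
          break
        }
      }
      if (!violated && !identical(beam[[1]]$tags, gold)) {
        gk <- .prefix_keys(sent, gold, n, ontology, feature_config, it$cache)
        pk <- .prefix_keys(sent, beam[[1]]$tags, n, ontology, feature_config,
                           it$cache)
        .env_add(wenv, gk, 1); .env_add(uenv, gk, cnt)
        .env_add(wenv, pk, -1); .env_add(uenv, pk, -cnt)
      }
    }
  }
  w <- snapshot(wenv)
  u <- snapshot(uenv)
  avg <- w
  if (length(w)) avg <- w - u[names(w)] / cnt
  model$weights <- w[w != 0]
  model$averaged_weights <- avg[avg != 0]
  model
}

#' @export
print.ner_model <- function(x, ...) {
  cat(sprintf("<ner_model: %d weights, %d averaged weights>\n",
              length(x$weights), length(x$averaged_weights)))
  invisible(x)
}

#' Materialize BIO tags as mentions
#'
#' Maximal B-I runs become mentions (DS = Disease, CD = Chemical) with
#' provenance `ner`. An orphan inside tag is repaired by treating it as a
#' begin tag (with a message).
#'
#' @param tags character vector of tags.
#' @param sentence the `cid_sentence` the tags align to.
#' @param text the document text (for mention surface strings).
#' @return mention data.frame.
#' @export
bio_to_mentions <- function(tags, sentence, text) {
  tok <- sentence$tokens
  stopifnot(length(tags) == nrow(tok))
  m <- empty_mentions()
  prev <- "O"
  run_start <- NA_integer_; run_type <- NA_character_
  flush <- function(m, a, b, type) {
    s <- tok$start[a]; e <- tok$end[b]
    rbind(m, data.frame(start = s, end = e,
                        text = substring(text, s + 1L, e),
                        type = type, concept_id = UNLINKED, provenance = "ner",
                        stringsAsFactors = FALSE))
  }
  for (i in seq_along(tags)) {
    t <- tags[i]
    code <- sub("^[BI]-", "", t)
    type <- if (code == "DS") "Disease" else "Chemical"
    if (startsWith(t, "I-") && !(prev %in% paste0(c("B-", "I-"), code))) {
      message("bio_to_mentions: orphan inside tag repaired as begin at token ", i)
      t <- paste0("B-", code)
    }
    if (startsWith(t, "B-") || t == "O") {
      if (!is.na(run_start)) m <- flush(m, run_start, i - 1L, run_type)
      run_start <- NA_integer_
    }
    if (startsWith(t, "B-")) { run_start <- i; run_type <- type }
    prev <- t
  }
  if (!is.na(run_start)) m <- flush(m, run_start, length(tags), run_type)
  m
}
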