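# Joint decoding of NER tags and concept assignments. The beam score of a
# tag sequence is the NER score plus a normalization (NEN) term per position:
#   * a begin tag contributes the best-concept score of the one-token span
#     starting there;
#   * an inside tag contributes the best-concept score of the growing span
#     re-scored with the current token appended;
#   * an O position contributes the constant `none_threshold`;
#   * when a completed span's best-concept score falls below
#     `none_threshold`, every position of that span retroactively
#     contributes the constant instead, and the span is emitted unlinked.
# With the default none_threshold = 0 the O/constant cases contribute
# nothing. Because below-threshold decoding adds the same constant at every
# position, setting none_threshold = +Inf makes the argmax identical to
# NER-only decoding; infinite thresholds are compared via the pair
# (number of constant positions, residual score).

#' Joint decoding configuration
#'
#' @param beam_width positive integer beam width.
#' @param none_threshold score below which a completed span is left unlinked;
#'   also the constant contributed by O and unlinked-span positions.
#'   `+Inf` degrades joint decoding to NER-only decoding; `-Inf` is not
#'   supported.
#' @param nen_scale scale factor applied to the NEN term (the NER and NEN
#'   scores are not inherently commensurate).
#' @return a list of class `joint_config`.
#' @export
joint_config <- function(beam_width = 5L, none_threshold = 0, nen_scale = 1) {
  if (beam_width < 1L) stop("beam_width must be >= 1")
  if (identical(none_threshold, -Inf)) stop("none_threshold = -Inf is not supported")
  structure(list(beam_width = as.integer(beam_width),
                 none_threshold = none_threshold, nen_scale = nen_scale),
            class = "joint_config")
}

#' Build a span scorer from the back-off normalizer
#'
#' Returns `function(tokens, type)` giving the best branch-matching concept
#' and its raw back-off score for a candidate span, as required by
#' [joint_decode()].
#'
#' @param ontology a `cid_ontology`.
#' @param ssi optional `ssi_model`.
#' @param emb optional `embedding_model`.
#' @param ssi_threshold,emb_threshold back-off stage thresholds.
#' @param memoize cache span scores (keyed by type and span text).
#' @return a scorer closure.
#' @export
make_span_scorer <- function(ontology, ssi = NULL, emb = NULL,
                             ssi_threshold = 0, emb_threshold = 0,
                             memoize = TRUE) {
  force(ontology); force(ssi); force(emb)
  cache <- if (memoize) new.env(hash = TRUE, parent = emptyenv())
  function(tokens, type) {
    text <- paste(tokens, collapse = " ")
    key <- paste0(type, "|", text)
    if (memoize && !is.null(cache[[key]])) return(cache[[key]])
    res <- normalize_backoff(text, type, ontology,
                             ssi = ssi, emb = emb,
                             ssi_threshold = ssi_threshold,
                             emb_threshold = emb_threshold,
                             none_threshold = -Inf)
    out <- list(concept_id = res$concept_id, score = res$score)
    if (memoize) cache[[key]] <- out
    out
  }
}

# state transition shared by the beam and by score_joint_sequence(); a state
# is list(tags, key, base, ncount, spans, cur) where cur tracks the open span
.joint_close <- function(st, end_idx, tau, scale) {
  cur <- st$cur
  if (is.null(cur)) return(st)
  linked <- is.finite(cur$raw_last) && cur$raw_last >= tau &&
    !is.na(cur$concept_last)
  if (!linked) {
    st$base <- st$base - cur$contrib
    st$ncount <- st$ncount + cur$len
  }
  st$spans[[length(st$spans) + 1L]] <- list(
    from = cur$start, to = end_idx, type = cur$type,
    concept_id = if (linked) cur$concept_last else NA_character_,
    score = cur$raw_last)
  st$cur <- NULL
  st
}

.joint_step <- function(st, sentence, i, tag, ner_inc, scorer, tau, scale) {
  st$tags <- c(st$tags, tag)
  st$key <- paste0(st$key, .TAG_KEY[[tag]])
  st$base <- st$base + ner_inc
  if (tag == "O") {
    st <- .joint_close(st, i - 1L, tau, scale)
    st$ncount <- st$ncount + 1L
  } else if (startsWith(tag, "B-")) {
    st <- .joint_close(st, i - 1L, tau, scale)
    type <- if (tag == "B-DS") "Disease" else "Chemical"
    res <- scorer(sentence$tokens$text[i], type)
    contrib <- if (is.finite(res$score)) scale * res$score else 0
    st$base <- st$base + contrib
    st$cur <- list(start = i, type = type, contrib = contrib,
                   raw_last = res$score, concept_last = res$concept_id, len = 1L)
  } else { # inside tag growing the open span
    cur <- st$cur
    res <- scorer(sentence$tokens$text[cur$start:i], cur$type)
    contrib <- if (is.finite(res$score)) scale * res$score else 0
    st$base <- st$base + contrib
    cur$contrib <- cur$contrib + contrib
    cur$raw_last <- res$score
    cur$concept_last <- res$concept_id
    cur$len <- cur$len + 1L
    st$cur <- cur
  }
  st
}

# ranking keys: as-if-closed effective score (finite tau) or the pair
# (constant-position count, residual) for tau = +Inf
.joint_rank <- function(states, tau, scale) {
  pend_conv <- vapply(states, function(st) {
    !is.null(st$cur) &&
      (!is.finite(st$cur$raw_last) || st$cur$raw_last < tau ||
         is.na(st$cur$concept_last))
  }, logical(1))
  base <- vapply(states, `[[`, numeric(1), "base")
  ncnt <- vapply(states, `[[`, numeric(1), "ncount")
  clen <- vapply(states, function(st) if (is.null(st$cur)) 0 else st$cur$len,
                 numeric(1))
  ccon <- vapply(states, function(st) if (is.null(st$cur)) 0 else st$cur$contrib,
                 numeric(1))
  resid <- base - ifelse(pend_conv, ccon, 0)
  conv <- ncnt + ifelse(pend_conv, clen, 0)
  keys <- vapply(states, `[[`, character(1), "key")
  if (is.infinite(tau)) {
    order(-conv, -resid, keys, method = "radix")
  } else {
    order(-(resid + conv * scale * tau), keys, method = "radix")
  }
}

#' Jointly decode entity spans and concept ids for one sentence
#'
#' @param sentence a `cid_sentence`.
#' @param model a trained `ner_model`.
#' @param scorer a span scorer, e.g. from [make_span_scorer()].
#' @param config a [joint_config()].
#' @param ontology optional ontology for NER dictionary features.
#' @param text document text for mention surfaces (defaults to a
#'   space-joined reconstruction of the sentence tokens).
#' @param use_average decode with averaged perceptron weights.
#' @return list with `mentions` (data.frame; unlinked spans have concept id
#'   `-1`), `tags` and `score` (the effective joint score; for infinite
#'   `none_threshold` the residual NER score).
#' @export
joint_decode <- function(sentence, model, scorer, config = joint_config(),
                         ontology = NULL, text = NULL, use_average = TRUE) {
  stopifnot(inherits(config, "joint_config"))
  n <- nrow(sentence$tokens)
  if (is.null(text)) {
    text <- paste(rep(" ", 0), collapse = "")
    # reconstruct a text covering the token offsets
    if (n) {
      text <- strrep(" ", sentence$tokens$end[n])
      for (i in seq_len(n)) {
        substr(text, sentence$tokens$start[i] + 1L, sentence$tokens$end[i]) <-
          sentence$tokens$text[i]
      }
    }
  }
  if (n == 0L) {
    return(list(mentions = empty_mentions(), tags = character(), score = 0))
  }
  tau <- config$none_threshold; scale <- config$nen_scale
  w <- if (use_average) model$averaged_weights else model$weights
  cache <- new.env(hash = TRUE, parent = emptyenv())
  beam <- list(list(tags = character(), key = "", base = 0, ncount = 0L,
                    spans = list(), cur = NULL))
  for (i in seq_len(n)) {
    cand <- list()
    for (st in beam) {
      prev <- if (i == 1L) "O" else st$tags[i - 1L]
      f <- .ner_feats_cached(sentence, i, prev, ontology, model$feature_config, cache)
      for (tag in NER_TAGS) {
        if (i == 1L && startsWith(tag, "I-")) next
        if (!bio_valid_next(prev, tag)) next
        inc <- .wsum(w, paste0(tag, "|", f))
        cand[[length(cand) + 1L]] <-
          .joint_step(st, sentence, i, tag, inc, scorer, tau, scale)
      }
    }
    ord <- .joint_rank(cand, tau, scale)
    beam <- cand[ord[seq_len(min(config$beam_width, length(cand)))]]
  }
  beam <- lapply(beam, .joint_close, end_idx = n, tau = tau, scale = scale)
  best <- beam[[.joint_rank(beam, tau, scale)[1]]]
  mentions <- empty_mentions()
  for (sp in best$spans) {
    s <- sentence$tokens$start[sp$from]; e <- sentence$tokens$end[sp$to]
    mentions <- rbind(mentions, data.frame(
      start = s, end = e, text = substring(text, s + 1L, e), type = sp$type,
      concept_id = if (is.na(sp$concept_id)) UNLINKED else sp$concept_id,
      provenance = "ner", stringsAsFactors = FALSE))
  }
  score <- if (is.infinite(tau)) best$base else best$base + best$ncount * scale * tau
  list(mentions = mentions, tags = best$tags, score = score)
}

#' Score a complete tag sequence under the joint scoring function
#'
#' Applies exactly the transitions used by [joint_decode()], so exhaustive
#' enumeration over BIO-valid sequences can be compared against the beam.
#'
#' @inheritParams joint_decode
#' @param tags full tag sequence.
#' @param cache optional per-sentence feature memoization environment.
#' @return list with `base` (residual score), `ncount` (constant positions),
#'   `effective` (finite `none_threshold` only), `key` (tie-break key) and
#'   `spans`.
#' @export
score_joint_sequence <- function(sentence, model, tags, scorer,
                                 config = joint_config(), ontology = NULL,
                                 use_average = TRUE, cache = NULL) {
  tau <- config$none_threshold; scale <- config$nen_scale
  w <- if (use_average) model$averaged_weights else model$weights
  st <- list(tags = character(), key = "", base = 0, ncount = 0L,
             spans = list(), cur = NULL)
  prev <- "O"
  for (i in seq_along(tags)) {
    f <- .ner_feats_cached(sentence, i, prev, ontology, model$feature_config, cache)
    inc <- .wsum(w, paste0(tags[i], "|", f))
    st <- .joint_step(st, sentence, i, tags[i], inc, scorer, tau, scale)
    prev <- tags[i]
  }
  st <- .joint_close(st, length(tags), tau, scale)
  list(base = st$base, ncount = st$ncount,
       effective = if (is.infinite(tau)) NA_real_
                   else st$base + st$ncount * scale * tau,
       key = st$key, spans = st$spans)
}
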