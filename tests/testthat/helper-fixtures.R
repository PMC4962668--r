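# Shared fixtures and independent oracles. Expensive objects are memoized in
# a session-local environment so test files can share them.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder()
  .fx_cache[[name]]
}

fx_cfg <- function() fixture_config(seed = 7)
fx_ontology <- function() fx("ontology", function() make_ontology(fx_cfg()))
fx_docs <- function() fx("docs", function() make_documents(fx_cfg(), fx_ontology()))
fx_sep <- function() fx("sep", function() make_separable_corpus(1))
fx_ner_model <- function() {
  fx("ner_model", function() train_perceptron(fx_sep(), epochs = 5, seed = 1))
}
fx_ssi_identity <- function() {
  fx("ssi0", function() train_ssi(list(), fx_ontology(), epochs = 0))
}

# independent oracle: exhaustive enumeration of all BIO-valid tag sequences
enum_bio_sequences <- function(n) {
  tags <- c("O", "B-CD", "B-DS", "I-CD", "I-DS")
  valid <- function(prev, tag) {
    if (tag == "I-CD") return(prev %in% c("B-CD", "I-CD"))
    if (tag == "I-DS") return(prev %in% c("B-DS", "I-DS"))
    TRUE
  }
  seqs <- list(character(0))
  for (i in seq_len(n)) {
    out <- list()
    for (s in seqs) {
      prev <- if (i == 1L) "O" else s[i - 1L]
      for (tag in tags) {
        if (i == 1L && startsWith(tag, "I-")) next
        if (!valid(prev, tag)) next
        out[[length(out) + 1L]] <- c(s, tag)
      }
    }
    seqs <- out
  }
  seqs
}

tag_sort_key <- function(tags) {
  key <- c("O" = "a", "B-CD" = "b", "B-DS" = "c", "I-CD" = "d", "I-DS" = "e")
  paste(key[tags], collapse = "")
}

# a bare sentence from a token vector, with fixture POS tags and no parse
toy_sentence <- function(tokens, pos = NULL) {
  starts <- c(0L, cumsum(nchar(tokens) + 1L))[seq_along(tokens)]
  tok <- data.frame(text = tokens, start = starts, end = starts + nchar(tokens),
                    stringsAsFactors = FALSE)
  tok$stem <- vapply(tolower(tokens), sievecid::porter_stem, character(1),
                     USE.NAMES = FALSE)
  tok$pos <- if (is.null(pos)) rep(NA_character_, nrow(tok)) else pos
  structure(list(tokens = tok,
                 deps = data.frame(head = integer(), dep = integer(),
                                   label = character(), stringsAsFactors = FALSE),
                 root = NA_integer_),
            class = "cid_sentence")
}

# document planting canonical coreference cases: a same-id disease pair,
# a token-overlap chemical pair, and an anaphoric "side effect"
fx_canonical_doc <- function() {
  fx("canonical_doc", function() {
    conc <- data.frame(id = c("D001145", "D002121"), branch = c("C", "D"),
                       preferred_name = c("arrhythmia", "verapamil"),
                       stringsAsFactors = FALSE)
    ont <- sievecid:::build_ontology(conc, list(D001145 = "arrhythmia",
                                                D002121 = "verapamil"))
    d <- new_document(
      "3323259", "Irregular heartbeat and irregular heart beat after treatment.",
      paste("Calcium channel blocking agents were used.",
            "Calcium channel blockers reduced pressure.",
            "Hemorrhagic cystitis developed.",
            "The side effect resolved."),
      mentions = data.frame(
        start = c(0L, 24L, 62L, 148L), end = c(19L, 44L, 93L, 168L),
        text = c("Irregular heartbeat", "irregular heart beat",
                 "Calcium channel blocking agents", "Hemorrhagic cystitis"),
        type = c("Disease", "Disease", "Chemical", "Disease"),
        concept_id = c("D001145", "D001145", "D002121", "D002122"),
        provenance = "gold", stringsAsFactors = FALSE))
    conllu <- unlist(lapply(d$sentences, function(s) {
      toks <- s$tokens$text
      vmap <- c(and = "CC", after = "IN", were = "VBD", developed = "VBD",
                used = "VBD", resolved = "VBD", reduced = "VBD",
                The = "DT", the = "DT")
      pos <- ifelse(toks %in% names(vmap), vmap[toks],
                    ifelse(toks == ".", ".", "NN"))
      c(vapply(seq_along(toks), function(i)
        paste(i, toks[i], tolower(toks[i]), pos[i], "_", "_",
              if (i == 1) 0 else i - 1, if (i == 1) "root" else "dep",
              "_", "_", sep = "\t"), character(1)), "")
    }))
    list(doc = attach_parses(d, conllu), ontology = ont)
  })
}

# random NER model over the features observable in a set of sentences
random_ner_model <- function(sents, seed = 4) {
  set.seed(seed)
  tags <- c("O", "B-CD", "B-DS", "I-CD", "I-DS")
  feats <- unique(unlist(lapply(sents, function(s) {
    unlist(lapply(seq_len(nrow(s$tokens)), function(i) {
      unlist(lapply(tags, function(p)
        paste0(tags, "|", extract_ner_features(s, i, p))))
    }))
  })))
  w <- stats::setNames(stats::rnorm(length(feats)), feats)
  structure(list(weights = w, averaged_weights = w, feature_config = NULL),
            class = "ner_model")
}
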