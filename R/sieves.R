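# The sieve cascade itself. Candidate pairs are all unordered pairs drawn
# from the document's entity mentions and noun phrases; each sieve examines
# the pairs no earlier sieve kept. Mentions of two different entity types
# are never merged.

.coref_items <- function(doc) {
  items <- data.frame(kind = character(), start = integer(), end = integer(),
                      text = character(), type = character(),
                      concept_id = character(), sentence_index = integer(),
                      head_text = character(), mention_row = integer(),
                      stringsAsFactors = FALSE)
  m <- doc$mentions
  for (j in seq_len(nrow(m))) {
    si <- sentence_of_offset(doc, m$start[j])
    w <- sc_words(m$text[j])
    items <- rbind(items, data.frame(
      kind = "mention", start = m$start[j], end = m$end[j], text = m$text[j],
      type = m$type[j], concept_id = m$concept_id[j], sentence_index = si,
      head_text = tolower(w[length(w)]), mention_row = j,
      stringsAsFactors = FALSE))
  }
  for (k in seq_along(doc$sentences)) {
    nps <- chunk_noun_phrases(doc$sentences[[k]])
    for (j in seq_len(nrow(nps))) {
      # drop NPs whose span coincides with an existing mention
      if (nrow(m) && any(m$start == nps$start[j] & m$end == nps$end[j])) next
      txt <- substring(doc$text, nps$start[j] + 1L, nps$end[j])
      w <- sc_words(txt)
      items <- rbind(items, data.frame(
        kind = "np", start = nps$start[j], end = nps$end[j], text = txt,
        type = NA_character_, concept_id = NA_character_, sentence_index = k,
        head_text = tolower(w[length(w)]), mention_row = NA_integer_,
        stringsAsFactors = FALSE))
    }
  }
  items
}

.linked <- function(id) !is.na(id) & id != UNLINKED

# ID-match criterion shared by sieves 3-7: does any variant of one side
# resolve in the ontology to the other side's concept id?
.variant_id_match <- function(a, b, items, ontology, variant_fun, stemmed = FALSE) {
  for (pair in list(c(a, b), c(b, a))) {
    other_id <- items$concept_id[pair[2]]
    if (!.linked(other_id)) next
    for (v in variant_fun(items$text[pair[1]])) {
      if (other_id %in% ontology_lookup(ontology, v, stemmed = stemmed)) return(TRUE)
    }
  }
  FALSE
}

.sieve_predicates <- function(items, ontology, abbrev, hypo) {
  stems <- lapply(items$text, function(tx)
    unique(vapply(sc_strip_determiners(sc_words(tolower(tx))), porter_stem,
                  character(1))))
  shared_count <- function(a, b) length(intersect(stems[[a]], stems[[b]]))

  list(
    # 1: identical concept id from normalization
    function(a, b) {
      .linked(items$concept_id[a]) && .linked(items$concept_id[b]) &&
        items$concept_id[a] == items$concept_id[b]
    },
    # 2: abbreviation / long form pair
    function(a, b) {
      if (!length(abbrev)) return(FALSE)
      ta <- tolower(items$text[a]); tb <- tolower(items$text[b])
      short <- tolower(names(abbrev)); long <- tolower(abbrev)
      any(short == ta & long == tb) || any(short == tb & long == ta)
    },
    # 3: grammatical conversion + ID match
    function(a, b) .variant_id_match(a, b, items, ontology, grammatical_variants),
    # 4: number replacement + ID match
    function(a, b) .variant_id_match(a, b, items, ontology, number_variants),
    # 5: synonym replacement: one side's surface is a dictionary synonym of
    # the other side's concept
    function(a, b) {
      for (pair in list(c(a, b), c(b, a))) {
        other_id <- items$concept_id[pair[2]]
        if (.linked(other_id) &&
            other_id %in% ontology_lookup(ontology, items$text[pair[1]])) {
          return(TRUE)
        }
      }
      FALSE
    },
    # 6: affix normalization + ID match
    function(a, b) .variant_id_match(a, b, items, ontology, phrase_affix_variants),
    # 7: stemming + ID match against the stemmed ontology index; like the
    # other variant sieves, stemming must actually transform the phrase
    # (a phrase its own stem leaves unchanged was already testable raw)
    function(a, b) {
      for (pair in list(c(a, b), c(b, a))) {
        other_id <- items$concept_id[pair[2]]
        if (!.linked(other_id)) next
        tx <- items$text[pair[1]]
        if (sc_stem_phrase(tx) == paste(sc_words(tolower(tx)), collapse = " ")) next
        if (other_id %in% ontology_lookup(ontology, tx, stemmed = TRUE)) return(TRUE)
      }
      FALSE
    },
    # 8: partial match: mutual-maximal stemmed-token overlap, at least two
    # shared stems covering at least half of the shorter phrase, and a
    # genuinely partial overlap (each side keeps an unshared informative
    # stem, so permutations and containments are left to the variant sieves;
    # number-form tokens are ignored as uninformative)
    function(a, b) {
      n <- nrow(items)
      pm_stems <- lapply(stems, function(s) s[is.na(vapply(s, .number_value, integer(1)))])
      sab <- length(intersect(pm_stems[[a]], pm_stems[[b]]))
      if (sab < 2L) return(FALSE)
      if (sab < min(length(pm_stems[[a]]), length(pm_stems[[b]])) / 2) return(FALSE)
      if (!length(setdiff(pm_stems[[a]], pm_stems[[b]])) ||
          !length(setdiff(pm_stems[[b]], pm_stems[[a]]))) return(FALSE)
      ov <- function(x, y) length(intersect(pm_stems[[x]], pm_stems[[y]]))
      best_a <- max(vapply(setdiff(seq_len(n), a), function(x) ov(a, x), numeric(1)))
      best_b <- max(vapply(setdiff(seq_len(n), b), function(x) ov(b, x), numeric(1)))
      sab >= best_a || sab >= best_b
    },
    # 9: hyponym term near a typed mention (handled pairwise: one side is a
    # dictionary hyponym, the other the nearest matching typed mention)
    function(a, b) {
      for (pair in list(c(a, b), c(b, a))) {
        h <- pair[1]; e <- pair[2]
        txt <- paste(sc_strip_determiners(sc_words(tolower(items$text[h]))),
                     collapse = " ")
        wanted <- if (txt %in% hypo$disease_terms) "Disease"
                  else if (txt %in% hypo$chemical_terms) "Chemical"
                  else next
        if (is.na(items$type[e]) || items$type[e] != wanted) next
        d <- items$sentence_index[e] - items$sentence_index[h]
        if (abs(d) > hypo$window_sentences) next
        # nearest preceding entity first, then nearest following
        cand <- which(items$kind == "mention" & !is.na(items$type) &
                        items$type == wanted &
                        abs(items$sentence_index - items$sentence_index[h]) <=
                          hypo$window_sentences &
                        seq_len(nrow(items)) != h)
        if (!length(cand)) next
        delta <- items$sentence_index[cand] - items$sentence_index[h]
        pre <- cand[delta <= 0]
        pick <- if (length(pre)) pre[which.max(items$sentence_index[pre])]
                else cand[which.min(items$sentence_index[cand])]
        if (pick == e) return(TRUE)
      }
      FALSE
    }
  )
}

#' Run the nine-pass sieve cascade on a document
#'
#' @param doc a `cid_document` (mentions normalized where possible; POS
#'   attached for NP chunking).
#' @param ontology a `cid_ontology`.
#' @param abbrev abbreviation map from [find_abbreviations()]; computed from
#'   the document when `NULL`.
#' @param hypo a [hyponym_dictionaries()].
#' @param sieves integer vector of enabled sieve indices (subset of 1:9, in
#'   cascade order).
#' @return object of class `coref_clusters`: `items` (the mention/NP pool),
#'   `kept` (pair decisions with the sieve index that kept each pair), and
#'   `clusters` (list of integer vectors indexing `items`).
#' @export
run_sieves <- function(doc, ontology, abbrev = NULL,
                       hypo = hyponym_dictionaries(), sieves = 1:9) {
  if (is.null(abbrev)) abbrev <- find_abbreviations(doc)
  items <- .coref_items(doc)
  kept <- data.frame(a = integer(), b = integer(), sieve = integer())
  n <- nrow(items)
  if (n >= 2L) {
    preds <- .sieve_predicates(items, ontology, abbrev, hypo)
    alive <- utils::combn(n, 2L)
    type_conflict <- apply(alive, 2L, function(p) {
      ta <- items$type[p[1]]; tb <- items$type[p[2]]
      !is.na(ta) && !is.na(tb) && ta != tb
    })
    alive <- alive[, !type_conflict, drop = FALSE]
    for (k in sort(sieves)) {
      if (!ncol(alive)) break
      hit <- apply(alive, 2L, function(p) preds[[k]](p[1], p[2]))
      if (any(hit)) {
        kept <- rbind(kept, data.frame(a = alive[1, hit], b = alive[2, hit],
                                       sieve = k))
        alive <- alive[, !hit, drop = FALSE]
      }
    }
  }
  clusters <- list()
  if (n) {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (nrow(kept)) g <- igraph::add_edges(g, rbind(kept$a, kept$b))
    comp <- igraph::components(g)$membership
    clusters <- unname(split(seq_len(n), comp))
  }
  structure(list(items = items, kept = kept, clusters = clusters,
                 pmid = doc$pmid),
            class = "coref_clusters")
}

#' @export
print.coref_clusters <- function(x, ...) {
  nontrivial <- sum(lengths(x$clusters) > 1L)
  cat(sprintf("<coref_clusters %s: %d items, %d kept pairs, %d non-singleton clusters>\n",
              x$pmid, nrow(x$items), nrow(x$kept), nontrivial))
  invisible(x)
}

#' Kept-pair audit table
#'
#' @param clusters a `coref_clusters`.
#' @return data.frame with the two pair texts and the sieve that kept them.
#' @export
kept_pairs <- function(clusters) {
  k <- clusters$kept
  data.frame(text_a = clusters$items$text[k$a],
             text_b = clusters$items$text[k$b],
             sieve = k$sieve, stringsAsFactors = FALSE)
}

#' Propagate entity labels through coreference clusters
#'
#' Every noun phrase sharing a cluster with typed, linked mentions becomes a
#' mention of the majority type and concept id (ties resolved by the
#' earliest mention), with provenance `coref`. Existing mentions are never
#' modified.
#'
#' @param doc a `cid_document`.
#' @param clusters result of [run_sieves()].
#' @return the document with propagated mentions appended.
#' @export
propagate_entity_labels <- function(doc, clusters) {
  items <- clusters$items
  majority <- function(vals, starts) {
    tab <- table(vals)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) return(top)
    # tie: value of the earliest mention among the tied ones
    cand <- vals %in% top
    vals[cand][which.min(starts[cand])]
  }
  for (cl in clusters$clusters) {
    typed <- cl[items$kind[cl] == "mention" & !is.na(items$type[cl])]
    linked <- typed[.linked(items$concept_id[typed])]
    if (!length(typed)) next
    types <- items$type[typed]
    if (length(unique(types)) > 1L) {
      tab <- table(types)
      if (sum(tab == max(tab)) > 1L) {
        message("propagate_entity_labels: type conflict without majority in cluster; skipped")
        next
      }
    }
    cl_type <- majority(types, items$start[typed])
    cl_id <- if (length(linked))
      majority(items$concept_id[linked], items$start[linked]) else UNLINKED
    for (x in cl[items$kind[cl] == "np"]) {
      already <- nrow(doc$mentions) &&
        any(doc$mentions$start == items$start[x] & doc$mentions$end == items$end[x])
      if (already) next
      doc$mentions <- rbind(doc$mentions, data.frame(
        start = items$start[x], end = items$end[x], text = items$text[x],
        type = cl_type, concept_id = cl_id, provenance = "coref",
        stringsAsFactors = FALSE))
    }
  }
  doc$mentions <- doc$mentions[order(doc$mentions$start, doc$mentions$end), ,
                               drop = FALSE]
  rownames(doc$mentions) <- NULL
  doc
}
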