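# Five-step distant-supervision corpus construction: filter the curated
# relation table to marker/mechanism (M) evidence, collect the referenced
# abstracts, drop abstracts overlapping an exclusion list, dictionary-tag
# chemical and disease mentions, and keep the sentences witnessing a curated
# pair. The result is a sentence-level "silver" corpus.

#' Step 1: keep only marker/mechanism relations
#'
#' @param table curated-relation data.frame (see [read_ctd_table()]).
#' @return the rows with `evidence == "M"`, order preserved.
#' @export
filter_relations <- function(table) {
  table[table$evidence == "M", , drop = FALSE]
}

#' Step 2: collect referenced abstracts
#'
#' Resolves the union of the relations' referencing PMIDs against an
#' abstract store; each returned document carries, as gold relations, the
#' subset of input relations that reference it. Missing PMIDs are reported
#' with a message and skipped.
#'
#' @param relations curated-relation data.frame (typically the output of
#'   [filter_relations()]).
#' @param store data.frame with columns `pmid`, `title`, `abstract`.
#' @return list of `cid_document` (no mentions yet).
#' @export
collect_abstracts <- function(relations, store) {
  wanted <- unique(unlist(relations$pmids, use.names = FALSE))
  if (!nrow(store)) {
    warning("abstract store is empty; no documents collected")
    return(list())
  }
  missing <- setdiff(wanted, store$pmid)
  if (length(missing)) {
    message("collect_abstracts: ", length(missing), " referenced pmid(s) not in store: ",
            paste(utils::head(missing, 5L), collapse = ", "))
  }
  found <- wanted[wanted %in% store$pmid]
  lapply(found, function(p) {
    row <- match(p, store$pmid)
    refs <- vapply(relations$pmids, function(ps) p %in% ps, logical(1))
    rel <- unique(data.frame(chemical_id = relations$chemical_id[refs],
                             disease_id = relations$disease_id[refs],
                             stringsAsFactors = FALSE))
    new_document(p, store$title[row], store$abstract[row], relations = rel)
  })
}

#' Step 3: remove abstracts overlapping an exclusion list
#'
#' @param docs list of `cid_document`.
#' @param excluded_pmids character vector of PMIDs to drop.
#' @return the documents whose pmid is not excluded, order preserved.
#' @export
remove_overlap <- function(docs, excluded_pmids) {
  docs[!vapply(docs, function(d) d$pmid %in% excluded_pmids, logical(1))]
}

#' Step 4: dictionary-annotate chemical and disease mentions
#'
#' Case-insensitive leftmost-longest matching of ontology surface forms at
#' token boundaries; matches become mentions carrying the matched concept id.
#' Overlapping shorter candidates are suppressed.
#'
#' @param docs list of `cid_document`.
#' @param ontology a `cid_ontology`.
#' @param max_tokens longest surface form considered, in tokens.
#' @return the documents with mentions attached.
#' @export
annotate_mentions <- function(docs, ontology, max_tokens = 6L) {
  lapply(docs, function(doc) {
    mentions <- empty_mentions()
    for (sent in doc$sentences) {
      tok <- sent$tokens
      n <- nrow(tok)
      i <- 1L
      while (i <= n) {
        hit_len <- 0L; hit_ids <- character()
        for (L in rev(seq_len(min(max_tokens, n - i + 1L)))) {
          phrase <- substring(doc$text, tok$start[i] + 1L, tok$end[i + L - 1L])
          ids <- ontology_lookup(ontology, phrase)
          if (length(ids)) { hit_len <- L; hit_ids <- ids; break }
        }
        if (hit_len) {
          id <- sort(hit_ids)[1]
          branch <- concept_branch(ontology, id)
          mentions <- rbind(mentions, data.frame(
            start = tok$start[i], end = tok$end[i + hit_len - 1L],
            text = substring(doc$text, tok$start[i] + 1L, tok$end[i + hit_len - 1L]),
            type = if (branch == "C") "Disease" else "Chemical",
            concept_id = id, provenance = "gold", stringsAsFactors = FALSE))
          i <- i + hit_len
        } else {
          i <- i + 1L
        }
      }
    }
    doc$mentions <- normalize_mentions(mentions)
    doc
  })
}

#' Step 5: keep sentences witnessing a curated pair
#'
#' A sentence is kept when it contains at least one chemical and one disease
#' mention whose id pair is in the document's curated relation set (set
#' `strict = FALSE` to relax this to type-only co-occurrence). Kept
#' sentences are emitted as standalone single-sentence documents with
#' sentence-local offsets.
#'
#' @param docs list of annotated `cid_document`.
#' @param strict require the co-occurring pair to be a curated pair.
#' @return list with `corpus` (list of sentence documents) and `stats`
#'   (a `silver_stats` count list).
#' @export
filter_sentences <- function(docs, strict = TRUE) {
  corpus <- list()
  chem_n <- 0L; dis_n <- 0L; inst_n <- 0L
  for (doc in docs) {
    m <- doc$mentions
    sent_of <- if (nrow(m))
      vapply(m$start, function(s) sentence_of_offset(doc, s), integer(1))
      else integer()
    for (k in seq_along(doc$sentences)) {
      tokens <- doc$sentences[[k]]$tokens
      if (!nrow(tokens)) next
      rows <- which(sent_of == k)
      chems <- rows[m$type[rows] == "Chemical"]
      diss <- rows[m$type[rows] == "Disease"]
      if (!length(chems) || !length(diss)) next
      pairs <- expand.grid(chem = chems, dis = diss)
      gold <- paste(doc$relations$chemical_id, doc$relations$disease_id)
      witness <- paste(m$concept_id[pairs$chem], m$concept_id[pairs$dis]) %in% gold
      if (strict && !any(witness)) next
      base <- tokens$start[1]
      sent_text <- substring(doc$text, base + 1L, tokens$end[nrow(tokens)])
      local_m <- m[rows, , drop = FALSE]
      local_m$start <- local_m$start - base
      local_m$end <- local_m$end - base
      rel <- unique(data.frame(
        chemical_id = m$concept_id[pairs$chem[witness]],
        disease_id = m$concept_id[pairs$dis[witness]],
        stringsAsFactors = FALSE))
      corpus[[length(corpus) + 1L]] <-
        new_document(paste0(doc$pmid, ".", k), sent_text, "",
                     mentions = local_m, relations = rel)
      chem_n <- chem_n + length(chems)
      dis_n <- dis_n + length(diss)
      inst_n <- inst_n + sum(witness)
    }
  }
  stats <- structure(list(sentences_kept = length(corpus),
                          chemical_mentions = chem_n,
                          disease_mentions = dis_n,
                          relation_instances = inst_n),
                     class = "silver_stats")
  list(corpus = corpus, stats = stats)
}

#' Build the silver corpus end to end
#'
#' Composition of the five construction steps; deterministic.
#'
#' @param table curated-relation data.frame.
#' @param store abstract store data.frame (`pmid`, `title`, `abstract`).
#' @param excluded_pmids PMIDs to exclude (e.g. an evaluation corpus).
#' @param ontology a `cid_ontology` used for dictionary annotation.
#' @param strict see [filter_sentences()].
#' @return list with `corpus` and `stats`; `stats` additionally records the
#'   number of curated relations kept, pmids collected and pmids removed by
#'   the overlap filter.
#' @export
build_silver <- function(table, store, excluded_pmids, ontology, strict = TRUE) {
  rel <- filter_relations(table)
  docs <- collect_abstracts(rel, store)
  kept <- remove_overlap(docs, excluded_pmids)
  ann <- annotate_mentions(kept, ontology)
  res <- filter_sentences(ann, strict = strict)
  res$stats$relations_kept <- nrow(rel)
  res$stats$pmids_collected <- length(docs)
  res$stats$pmids_removed <- length(docs) - length(kept)
  res
}

#' @export
print.silver_stats <- function(x, ...) {
  cat("<silver_stats>\n")
  for (nm in names(x)) cat(sprintf("  %s: %d\n", nm, x[[nm]]))
  invisible(x)
}
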