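# BioCreative-style evaluation: micro-averaged precision/recall/F1 for
# disease NER (span- or id-level) and for abstract-level CID pairs, plus
# the end-to-end pipeline driver.

#' Precision, recall and F1 from match counts
#'
#' Zero denominators yield 0 by convention (never an error).
#'
#' @param tp,fp,fn non-negative integer counts.
#' @return list of class `prf` with `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
prf <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be non-negative")
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f),
            class = "prf")
}

#' @export
print.prf <- function(x, ...) {
  cat(sprintf("P = %.4f  R = %.4f  F1 = %.4f  (tp %d, fp %d, fn %d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

.match_docs <- function(pred, gold) {
  pp <- vapply(pred, `[[`, character(1), "pmid")
  gp <- vapply(gold, `[[`, character(1), "pmid")
  missing <- setdiff(gp, pp)
  extra <- setdiff(pp, gp)
  if (length(missing) || length(extra)) {
    stop("pmid mismatch between prediction and gold sets; missing: ",
         paste(missing, collapse = ", "), "; unexpected: ",
         paste(extra, collapse = ", "))
  }
  pred[match(gp, pp)]
}

#' Evaluate disease NER (span or id level)
#'
#' Disease mentions only (the BioCreative DNER convention). At span level a
#' prediction matches on exact (start, end); at id level the distinct
#' disease concept ids per document are compared as sets, with unlinked
#' mentions excluded.
#'
#' @param pred,gold lists of `cid_document` over the same pmids.
#' @param level `"span"` or `"id"`.
#' @return a [prf()] object (micro-averaged).
#' @export
evaluate_dner <- function(pred, gold, level = c("span", "id")) {
  level <- match.arg(level)
  pred <- .match_docs(pred, gold)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(gold)) {
    keyset <- function(doc) {
      m <- doc$mentions[doc$mentions$type == "Disease", , drop = FALSE]
      if (level == "span") {
        unique(paste(m$start, m$end))
      } else {
        unique(m$concept_id[m$concept_id != UNLINKED])
      }
    }
    p <- keyset(pred[[i]]); g <- keyset(gold[[i]])
    tp <- tp + length(intersect(p, g))
    fp <- fp + length(setdiff(p, g))
    fn <- fn + length(setdiff(g, p))
  }
  prf(tp, fp, fn)
}

#' Evaluate abstract-level CID predictions
#'
#' Per-document set comparison of ordered (chemical id, disease id) pairs,
#' micro-averaged over documents.
#'
#' @param pred,gold named lists: pmid -> data.frame with columns
#'   `chemical_id`, `disease_id` (or lists of `cid_document`, whose
#'   `relations` are used).
#' @return a [prf()] object.
#' @export
evaluate_cid <- function(pred, gold) {
  as_sets <- function(x) {
    if (length(x) && inherits(x[[1]], "cid_document")) {
      stats::setNames(lapply(x, function(d)
        unique(paste(d$relations$chemical_id, d$relations$disease_id))),
        vapply(x, `[[`, character(1), "pmid"))
    } else {
      lapply(x, function(r) unique(paste(r$chemical_id, r$disease_id)))
    }
  }
  p <- as_sets(pred); g <- as_sets(gold)
  missing <- setdiff(names(g), names(p))
  if (length(missing)) {
    stop("pmid mismatch: no predictions for ", paste(missing, collapse = ", "))
  }
  tp <- 0L; fp <- 0L; fn <- 0L
  for (pm in names(g)) {
    pp <- p[[pm]]; gg <- g[[pm]]
    tp <- tp + length(intersect(pp, gg))
    fp <- fp + length(setdiff(pp, gg))
    fn <- fn + length(setdiff(gg, pp))
  }
  for (pm in setdiff(names(p), names(g))) fp <- fp + length(p[[pm]])
  prf(tp, fp, fn)
}

#' Run the full extraction pipeline on a corpus
#'
#' Stages: (joint) entity recognition and normalization, sieve coreference
#' with label propagation, intra-sentence candidate classification and
#' abstract-level aggregation. With `use_gold_mentions = TRUE` the DNER
#' stage is bypassed and the documents' own mentions are used, which
#' isolates the relation stage.
#'
#' @param docs list of `cid_document`.
#' @param relation_model a `relation_model`.
#' @param ontology a `cid_ontology`.
#' @param ner_model an `ner_model` (required unless `use_gold_mentions`).
#' @param scorer span scorer from [make_span_scorer()] (joint decoding);
#'   `NULL` decodes NER-only and leaves mentions unlinked.
#' @param config a [joint_config()].
#' @param use_gold_mentions bypass the DNER stage.
#' @param use_coref enable sieve coreference propagation.
#' @param hypo hyponym dictionaries for sieve 9.
#' @param verbose log per-stage counts to stderr.
#' @return named list pmid -> data.frame (`chemical_id`, `disease_id`).
#' @export
run_pipeline <- function(docs, relation_model, ontology, ner_model = NULL,
                         scorer = NULL, config = joint_config(),
                         use_gold_mentions = FALSE, use_coref = TRUE,
                         hypo = hyponym_dictionaries(), verbose = FALSE) {
  if (!use_gold_mentions && is.null(ner_model)) {
    stop("ner_model is required unless use_gold_mentions = TRUE")
  }
  out <- list()
  for (doc in docs) {
    if (!use_gold_mentions) {
      mentions <- empty_mentions()
      for (k in seq_along(doc$sentences)) {
        sent <- doc$sentences[[k]]
        if (!nrow(sent$tokens)) next
        if (is.null(scorer)) {
          dec <- beam_decode(sent, ner_model, config$beam_width, ontology)
          mentions <- rbind(mentions, bio_to_mentions(dec$tags, sent, doc$text))
        } else {
          dec <- joint_decode(sent, ner_model, scorer, config, ontology,
                              text = doc$text)
          mentions <- rbind(mentions, dec$mentions)
        }
      }
      doc$mentions <- normalize_mentions(mentions)
    }
    if (verbose) {
      message(sprintf("[%s] %d mentions after DNER stage", doc$pmid,
                      nrow(doc$mentions)))
    }
    pred <- predict_cid(doc, relation_model, ontology, use_coref = use_coref,
                        hypo = hypo)
    if (verbose) message(sprintf("[%s] %d predicted pairs", doc$pmid, nrow(pred)))
    out[[doc$pmid]] <- pred
  }
  out
}

#' Training instances for the relation classifier from annotated documents
#'
#' Every intra-sentence candidate becomes an instance; the label is `CID`
#' when the candidate's id pair is in the document's gold relation set and
#' `none` otherwise (distant sentence-level labeling).
#'
#' @param docs list of annotated `cid_document`.
#' @param feature_config passed to [extract_relation_features()].
#' @return list with `features` (list of named vectors) and `labels`.
#' @export
relation_training_data <- function(docs, feature_config = NULL) {
  features <- list(); labels <- character()
  for (doc in docs) {
    cands <- candidate_pairs(doc)
    if (!nrow(cands)) next
    gold <- paste(doc$relations$chemical_id, doc$relations$disease_id)
    m <- doc$mentions
    for (r in seq_len(nrow(cands))) {
      features[[length(features) + 1L]] <-
        extract_relation_features(doc, cands$chem[r], cands$dis[r], feature_config)
      key <- paste(m$concept_id[cands$chem[r]], m$concept_id[cands$dis[r]])
      labels <- c(labels, if (key %in% gold) "CID" else "none")
    }
  }
  list(features = features, labels = labels)
}
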