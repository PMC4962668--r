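# Document model and readers/writers for the plain-text formats the pipeline
# touches: PubTator corpora, CoNLL-U parses, ontology TSV and curated-relation
# TSV. All character offsets are 0-based half-open over the document text,
# which is `title + " " + abstract` (PubTator convention).

UNLINKED <- "-1"

MENTION_COLS <- c("start", "end", "text", "type", "concept_id", "provenance")

empty_mentions <- function() {
  data.frame(start = integer(), end = integer(), text = character(),
             type = character(), concept_id = character(),
             provenance = character(), stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(chemical_id = character(), disease_id = character(),
             stringsAsFactors = FALSE)
}

new_sentence <- function(tokens, deps = NULL, root = NA_integer_) {
  if (is.null(deps)) {
    deps <- data.frame(head = integer(), dep = integer(), label = character(),
                       stringsAsFactors = FALSE)
  }
  structure(list(tokens = tokens, deps = deps, root = root),
            class = "cid_sentence")
}

#' Construct a document
#'
#' Builds the full document object from raw title/abstract text: sentence
#' splitting, tokenization and stemming are applied; POS tags and dependency
#' parses are left empty until [attach_parses()] fills them.
#'
#' @param pmid document identifier (character).
#' @param title,abstract raw text. The document text used for all offsets is
#'   `paste(title, abstract)` with a single space separator.
#' @param mentions data.frame with columns start, end, text, type, concept_id,
#'   provenance (may be missing columns; defaults are filled).
#' @param relations data.frame with columns chemical_id, disease_id.
#' @return an object of class `cid_document`.
#' @export
new_document <- function(pmid, title, abstract = "", mentions = empty_mentions(),
                         relations = empty_relations()) {
  text <- if (nzchar(abstract)) paste(title, abstract) else title
  spans <- sc_split_sentences(title)
  if (nzchar(abstract)) {
    spans <- rbind(spans, sc_split_sentences(abstract, base = nchar(title) + 1L))
  }
  sentences <- vector("list", nrow(spans))
  for (k in seq_len(nrow(spans))) {
    seg <- substr(text, spans$start[k] + 1L, spans$end[k])
    tok <- sc_tokenize(seg, base = spans$start[k])
    tok$stem <- vapply(tolower(tok$text), porter_stem, character(1), USE.NAMES = FALSE)
    tok$pos <- NA_character_
    sentences[[k]] <- new_sentence(tok)
  }
  mentions <- normalize_mentions(mentions)
  validate_mentions(mentions, text, pmid)
  rownames(relations) <- NULL
  structure(list(pmid = as.character(pmid), title = title, abstract = abstract,
                 text = text, sentences = sentences, mentions = mentions,
                 relations = relations),
            class = "cid_document")
}

normalize_mentions <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(empty_mentions())
  if (is.null(m$concept_id)) m$concept_id <- UNLINKED
  if (is.null(m$provenance)) m$provenance <- "gold"
  m <- m[, MENTION_COLS]
  m$start <- as.integer(m$start); m$end <- as.integer(m$end)
  m <- m[order(m$start, m$end), , drop = FALSE]
  rownames(m) <- NULL
  m
}

validate_mentions <- function(m, text, pmid) {
  if (nrow(m) == 0L) return(invisible(TRUE))
  if (!all(m$type %in% c("Chemical", "Disease"))) {
    stop(sprintf("document %s: unknown mention type '%s'", pmid,
                 setdiff(m$type, c("Chemical", "Disease"))[1]))
  }
  got <- substring(text, m$start + 1L, m$end)
  bad <- which(got != m$text)
  if (length(bad)) {
    stop(sprintf(
      "document %s: mention text mismatch at offset %d: annotation '%s' vs text '%s'",
      pmid, m$start[bad[1]], m$text[bad[1]], got[bad[1]]))
  }
  invisible(TRUE)
}

#' @export
print.cid_document <- function(x, ...) {
  cat(sprintf("<cid_document %s: %d sentences, %d mentions, %d relations>\n",
              x$pmid, length(x$sentences), nrow(x$mentions), nrow(x$relations)))
  invisible(x)
}

# sentence index (1-based) containing a document-level character offset
sentence_of_offset <- function(doc, start) {
  for (k in seq_along(doc$sentences)) {
    tok <- doc$sentences[[k]]$tokens
    if (nrow(tok) && start >= tok$start[1] && start < tok$end[nrow(tok)]) return(k)
  }
  NA_integer_
}

# indices of tokens lying fully inside [start, end)
tokens_in_span <- function(sentence, start, end) {
  which(sentence$tokens$start >= start & sentence$tokens$end <= end)
}

#' Read a PubTator-format corpus
#'
#' Accepts text in the BioCreative distribution format: per document a
#' `PMID|t|title` line, a `PMID|a|abstract` line, tab-separated mention lines
#' (`PMID start end text type conceptID`) and relation lines
#' (`PMID CID chemicalID diseaseID`), with blank lines between documents.
#'
#' @param x path to a file, or a character vector of lines.
#' @return list of `cid_document`.
#' @export
read_pubtator <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  docs <- list()
  block <- character()
  flush <- function(block) {
    if (!length(block)) return(NULL)
    parse_pubtator_block(block)
  }
  for (ln in c(lines, "")) {
    if (!nzchar(trimws(ln))) {
      d <- flush(block)
      if (!is.null(d)) docs[[length(docs) + 1L]] <- d
      block <- character()
    } else {
      block <- c(block, ln)
    }
  }
  docs
}

parse_pubtator_block <- function(block) {
  tparts <- strsplit(block[1], "|", fixed = TRUE)[[1]]
  if (length(tparts) < 3L || tparts[2] != "t") {
    stop(sprintf("PubTator parse error: expected title line, got '%s'", block[1]))
  }
  pmid <- tparts[1]
  title <- paste(tparts[-(1:2)], collapse = "|")
  abstract <- ""
  rest <- block[-1]
  if (length(rest) && startsWith(rest[1], paste0(pmid, "|a|"))) {
    aparts <- strsplit(rest[1], "|", fixed = TRUE)[[1]]
    abstract <- paste(aparts[-(1:2)], collapse = "|")
    rest <- rest[-1]
  }
  mentions <- empty_mentions()
  relations <- empty_relations()
  for (ln in rest) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) >= 2L && f[2] == "CID") {
      if (length(f) < 4L) stop(sprintf("document %s: malformed relation line '%s'", pmid, ln))
      relations <- rbind(relations, data.frame(chemical_id = f[3], disease_id = f[4],
                                               stringsAsFactors = FALSE))
    } else if (length(f) >= 5L) {
      if (!(f[5] %in% c("Chemical", "Disease"))) {
        stop(sprintf("document %s: unknown annotation type '%s' in line '%s'", pmid, f[5], ln))
      }
      mentions <- rbind(mentions, data.frame(
        start = as.integer(f[2]), end = as.integer(f[3]), text = f[4], type = f[5],
        concept_id = if (length(f) >= 6L) f[6] else UNLINKED,
        provenance = "gold", stringsAsFactors = FALSE))
    } else {
      stop(sprintf("document %s: unparseable line '%s'", pmid, ln))
    }
  }
  new_document(pmid, title, abstract, mentions, relations)
}

#' Write documents in PubTator format
#'
#' Mention lines are sorted by start offset; unlinked mentions are written
#' with concept field `-1`.
#'
#' @param docs list of `cid_document`.
#' @param path optional file path; if `NULL` the lines are returned invisibly.
#' @return character vector of lines (invisibly when `path` is given).
#' @export
write_pubtator <- function(docs, path = NULL) {
  out <- character()
  for (doc in docs) {
    out <- c(out, sprintf("%s|t|%s", doc$pmid, doc$title),
             sprintf("%s|a|%s", doc$pmid, doc$abstract))
    m <- doc$mentions
    if (nrow(m)) {
      m <- m[order(m$start, m$end), , drop = FALSE]
      out <- c(out, sprintf("%s\t%d\t%d\t%s\t%s\t%s", doc$pmid, m$start, m$end,
                            m$text, m$type, m$concept_id))
    }
    r <- doc$relations
    if (nrow(r)) {
      out <- c(out, sprintf("%s\tCID\t%s\t%s", doc$pmid, r$chemical_id, r$disease_id))
    }
    out <- c(out, "")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Attach CoNLL-U parses to a document
#'
#' One blank-line-separated record group per sentence, in document order.
#' Columns used: ID, FORM, UPOS (or XPOS when UPOS is `_`), HEAD, DEPREL.
#' Token forms are verified against the document's own tokenization.
#'
#' @param doc a `cid_document`.
#' @param x path to a CoNLL-U file or a character vector of lines.
#' @return the document with POS tags and dependency arcs filled in.
#' @export
attach_parses <- function(doc, x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  groups <- list(); cur <- character()
  for (ln in c(lines, "")) {
    if (!nzchar(trimws(ln))) {
      if (length(cur)) groups[[length(groups) + 1L]] <- cur
      cur <- character()
    } else if (!startsWith(ln, "#")) {
      cur <- c(cur, ln)
    }
  }
  if (length(groups) != length(doc$sentences)) {
    stop(sprintf("document %s: %d parse groups for %d sentences",
                 doc$pmid, length(groups), length(doc$sentences)))
  }
  for (k in seq_along(groups)) {
    rows <- strsplit(groups[[k]], "\t", fixed = TRUE)
    sent <- doc$sentences[[k]]
    if (length(rows) != nrow(sent$tokens)) {
      stop(sprintf("document %s sentence %d: %d parse rows for %d tokens",
                   doc$pmid, k, length(rows), nrow(sent$tokens)))
    }
    heads <- integer(length(rows)); labels <- character(length(rows))
    for (i in seq_along(rows)) {
      f <- rows[[i]]
      if (f[2] != sent$tokens$text[i]) {
        stop(sprintf("document %s sentence %d: parse FORM '%s' != token '%s'",
                     doc$pmid, k, f[2], sent$tokens$text[i]))
      }
      pos <- f[4]
      if (identical(pos, "_") && length(f) >= 5L) pos <- f[5]
      sent$tokens$pos[i] <- pos
      heads[i] <- as.integer(f[7])
      labels[i] <- f[8]
    }
    sent$deps <- data.frame(head = heads, dep = seq_along(rows), label = labels,
                            stringsAsFactors = FALSE)
    sent$root <- which(heads == 0L)[1]
    doc$sentences[[k]] <- sent
  }
  doc
}

#' Serialize a document's parses as CoNLL-U lines
#' @param doc a `cid_document` with parses attached.
#' @return character vector of CoNLL-U lines.
#' @export
parses_to_conllu <- function(doc) {
  out <- character()
  for (sent in doc$sentences) {
    tok <- sent$tokens
    heads <- rep(0L, nrow(tok)); labels <- rep("root", nrow(tok))
    if (nrow(sent$deps)) {
      heads[sent$deps$dep] <- sent$deps$head
      labels[sent$deps$dep] <- sent$deps$label
    }
    for (i in seq_len(nrow(tok))) {
      out <- c(out, paste(i, tok$text[i], tok$stem[i],
                          ifelse(is.na(tok$pos[i]), "_", tok$pos[i]), "_", "_",
                          heads[i], labels[i], "_", "_", sep = "\t"))
    }
    out <- c(out, "")
  }
  out
}
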