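# Concept inventory standing in for the disease (C) and chemical (D) branches
# of a MeSH-like vocabulary, with a lowercased surface-form index and a
# Porter-stemmed index (used by the stemming sieve).

#' Load an ontology from TSV
#'
#' Expected columns: `id`, `branch` (`C` for diseases, `D` for chemicals),
#' `preferred_name`, `synonyms` (pipe-separated; the preferred name is added
#' to the synonym set if absent).
#'
#' @param x path to a TSV file or a character vector of lines.
#' @return an object of class `cid_ontology`.
#' @export
load_ontology <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  tab <- utils::read.delim(text = lines, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  req <- c("id", "branch", "preferred_name", "synonyms")
  if (!all(req %in% names(tab))) {
    stop("ontology TSV must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate concept id in ontology: ", tab$id[duplicated(tab$id)][1])
  }
  syn <- lapply(seq_len(nrow(tab)), function(i) {
    s <- strsplit(tab$synonyms[i], "|", fixed = TRUE)[[1]]
    unique(c(tab$preferred_name[i], s[nzchar(s)]))
  })
  names(syn) <- tab$id
  build_ontology(tab[, c("id", "branch", "preferred_name")], syn)
}

build_ontology <- function(concepts, synonyms) {
  stopifnot(all(concepts$branch %in% c("C", "D")))
  name_index <- list()
  stem_index <- list()
  for (i in seq_len(nrow(concepts))) {
    id <- concepts$id[i]
    for (s in synonyms[[id]]) {
      key <- tolower(s)
      name_index[[key]] <- unique(c(name_index[[key]], id))
      skey <- sc_stem_phrase(s)
      stem_index[[skey]] <- unique(c(stem_index[[skey]], id))
    }
  }
  structure(list(concepts = concepts, synonyms = synonyms,
                 name_index = name_index, stem_index = stem_index),
            class = "cid_ontology")
}

#' @export
print.cid_ontology <- function(x, ...) {
  cat(sprintf("<cid_ontology: %d concepts (%d disease, %d chemical), %d surface forms>\n",
              nrow(x$concepts), sum(x$concepts$branch == "C"),
              sum(x$concepts$branch == "D"), length(x$name_index)))
  invisible(x)
}

#' Look up a surface form in the ontology
#'
#' @param ontology a `cid_ontology`.
#' @param phrase surface string (matched lowercased; stem-wise when
#'   `stemmed = TRUE`).
#' @param stemmed use the Porter-stemmed index instead of the raw index.
#' @return character vector of concept ids (possibly empty).
#' @export
ontology_lookup <- function(ontology, phrase, stemmed = FALSE) {
  idx <- if (stemmed) ontology$stem_index else ontology$name_index
  key <- if (stemmed) sc_stem_phrase(phrase) else tolower(phrase)
  ids <- idx[[key]]
  if (is.null(ids)) character() else ids
}

concept_branch <- function(ontology, id) {
  b <- ontology$concepts$branch[match(id, ontology$concepts$id)]
  if (length(b)) b else NA_character_
}

branch_concepts <- function(ontology, branch) {
  ontology$concepts$id[ontology$concepts$branch == branch]
}

#' Serialize an ontology to TSV lines
#' @param ontology a `cid_ontology`.
#' @return character vector of TSV lines (with header).
#' @export
ontology_to_tsv <- function(ontology) {
  c("id\tbranch\tpreferred_name\tsynonyms",
    vapply(seq_len(nrow(ontology$concepts)), function(i) {
      id <- ontology$concepts$id[i]
      paste(id, ontology$concepts$branch[i], ontology$concepts$preferred_name[i],
            paste(ontology$synonyms[[id]], collapse = "|"), sep = "\t")
    }, character(1)))
}

#' Read a curated chemical-disease relation table from TSV
#'
#' Expected columns: `chemical_id`, `disease_id`, `evidence` (one of `M`,
#' `T`, `inferred`) and `pmids` (pipe-separated referencing PMIDs).
#'
#' @param x path to a TSV file or a character vector of lines.
#' @return data.frame with a `pmids` list column.
#' @export
read_ctd_table <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x, warn = FALSE) else x
  tab <- utils::read.delim(text = lines, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  req <- c("chemical_id", "disease_id", "evidence", "pmids")
  if (!all(req %in% names(tab))) {
    stop("curated-relation TSV must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(tab$evidence %in% c("M", "T", "inferred"))) {
    stop("evidence must be one of M, T, inferred")
  }
  tab$pmids <- lapply(strsplit(tab$pmids, "|", fixed = TRUE),
                      function(p) p[nzchar(p)])
  tab
}

#' Serialize a curated-relation table to TSV lines
#' @param table data.frame as returned by [read_ctd_table()].
#' @return character vector of TSV lines (with header).
#' @export
ctd_table_to_tsv <- function(table) {
  c("chemical_id\tdisease_id\tevidence\tpmids",
    vapply(seq_len(nrow(table)), function(i) {
      paste(table$chemical_id[i], table$disease_id[i], table$evidence[i],
            paste(table$pmids[[i]], collapse = "|"), sep = "\t")
    }, character(1)))
}
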